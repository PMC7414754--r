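#' Clade repertoire sizes per species
#'
#' Counts gene annotations per species per clade. The unique basis
#' collapses transcript-variant suffixes (\code{.1}, \code{.2}) so each
#' annotated gene counts once per species; the total basis counts every
#' transcript.
#'
#' @param transcripts data.frame with columns \code{species},
#'   \code{annotation}, \code{clade}
#' @param basis \code{"unique"} (default) or \code{"total"}
#' @return data.frame clade x species matrix of counts (clades as rows,
#'   first column \code{clade}); unassignable clades are counted under
#'   \code{"unplaced"}, never dropped
#' @export
cladeSizes <- function(transcripts, basis = c("unique", "total")) {
  basis <- match.arg(basis)
  x <- transcripts
  x$clade[is.na(x$clade) | !nzchar(x$clade)] <- "unplaced"
  if (basis == "unique") {
    x$annotation <- sub("\\.\\d+$", "", x$annotation)
    x <- x[!duplicated(paste(x$species, x$annotation, sep = "\r")), ,
           drop = FALSE]
  }
  tab <- table(x$clade, x$species)
  out <- as.data.frame.matrix(tab)
  out <- cbind(data.frame(clade = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Orthology-category fractions of the repertoire
#'
#' Percentages of transcripts in each orthology category, computed over
#' both bases: unique annotations (suffix ids collapsed, combination-IDs
#' counted once per species) and total transcripts. Each basis sums to
#' 100.
#'
#' @param transcripts data.frame with columns \code{species},
#'   \code{annotation}, \code{category}
#' @return data.frame (category, pct_unique, pct_total)
#' @export
categoryFractions <- function(transcripts) {
  cats <- c("reference_only", "non_orthologous", "low_orthology",
            "high_orthology")
  x <- transcripts
  ux <- x
  ux$annotation <- sub("\\.\\d+$", "", ux$annotation)
  ux <- ux[!duplicated(paste(ux$species, ux$annotation, sep = "\r")), ,
           drop = FALSE]
  pct <- function(d) {
    n <- nrow(d)
    vapply(cats, function(cc)
      if (n) 100 * sum(d$category == cc) / n else 0, numeric(1))
  }
  data.frame(category = cats, pct_unique = unname(pct(ux)),
             pct_total = unname(pct(x)), stringsAsFactors = FALSE)
}

#' Call gene losses in a focal species
#'
#' An orthogroup supports a loss call in the focal species iff the focal
#' species is absent from it and at least \code{minSupport} of the other
#' sequenced species are present. Each call is given a new gene id that
#' does not collide with any existing reference gene number (allocated
#' from max existing number + 1 upward), and is cross-referenced against a
#' supplied pseudogene table when one matches its orthogroup.
#'
#' @param ogs an \code{\linkS4class{OrthogroupSet}} with categories and
#'   clades assigned
#' @param focalSpecies the species whose losses are called (typically the
#'   reference species)
#' @param allSpecies character vector of every species analysed; the
#'   sequenced set is \code{setdiff(allSpecies, focalSpecies)}
#' @param refIds existing reference gene ids whose numbers must not be
#'   reused
#' @param minSupport minimum number of supporting sequenced species
#'   (default 3)
#' @param pseudogeneTable optional data.frame (orthogroup, pseudogene)
#' @param idPrefix prefix of newly allocated ids
#' @return data.frame (new_id, orthogroup, clade, support_species,
#'   n_support, pseudogene)
#' @export
callLosses <- function(ogs, focalSpecies, allSpecies, refIds,
                       minSupport = 3L, pseudogeneTable = NULL,
                       idPrefix = "Vmn1r") {
  if (!focalSpecies %in% allSpecies)
    stop("focal species '", focalSpecies, "' is not in the species set")
  sequenced <- setdiff(allSpecies, focalSpecies)
  tab <- ogs@table
  rows <- list()
  nums <- .refIdNum(refIds)
  nextId <- if (length(nums) && any(!is.na(nums)))
    max(nums, na.rm = TRUE) + 1 else 1
  for (i in seq_len(nrow(tab))) {
    sp <- strsplit(tab$species_set[i], ",", fixed = TRUE)[[1]]
    if (focalSpecies %in% sp) next
    supp <- intersect(sp, sequenced)
    if (length(supp) < minSupport) next
    pg <- NA_character_
    if (!is.null(pseudogeneTable)) {
      m <- match(tab$name[i], pseudogeneTable$orthogroup)
      if (!is.na(m)) pg <- pseudogeneTable$pseudogene[m]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      new_id = paste0(idPrefix, format(nextId, scientific = FALSE)),
      orthogroup = tab$name[i], clade = tab$clade[i],
      support_species = paste(sort(supp), collapse = ","),
      n_support = length(supp), pseudogene = pg,
      stringsAsFactors = FALSE)
    nextId <- nextId + 1
  }
  if (!length(rows))
    return(data.frame(new_id = character(), orthogroup = character(),
                      clade = character(), support_species = character(),
                      n_support = integer(), pseudogene = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Concentration of reference-only orthogroups in their modal clade
#'
#' @param ogs an \code{\linkS4class{OrthogroupSet}} with categories and
#'   clades assigned
#' @return list(n_reference_only, modal_clade, n_modal, percent) where
#'   percent is rounded half-up to the nearest integer, or NA when there
#'   are no reference-only groups
#' @examples
#' ## 50 of 53 reference-only groups in one clade -> 94 percent
#' @export
referenceOnlyConcentration <- function(ogs) {
  tab <- ogs@table
  ro <- tab[tab$category == "reference_only", , drop = FALSE]
  if (!nrow(ro))
    return(list(n_reference_only = 0L, modal_clade = NA_character_,
                n_modal = 0L, percent = NA_real_))
  cnt <- sort(table(ro$clade), decreasing = TRUE)
  list(n_reference_only = nrow(ro),
       modal_clade = names(cnt)[1],
       n_modal = as.integer(cnt[1]),
       percent = .roundHalfUp(100 * cnt[[1]] / nrow(ro), 0))
}
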