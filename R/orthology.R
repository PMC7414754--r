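#' Annotate transcripts with reference gene ids and variant suffixes
#'
#' Transcripts sharing a best-hit reference gene within one species receive
#' suffixes \code{.1, .2, ...} in descending alignment-score order (ties
#' broken by transcript id); a gene hit by a single transcript keeps the
#' bare gene id.
#'
#' @param hits data.frame with columns \code{id}, \code{species},
#'   \code{ref}, \code{hit_score} (as produced by
#'   \code{\link{mineReceptors}})
#' @return the input with an \code{annotation} column added
#' @examples
#' h <- data.frame(id = c("a", "b"), species = "spretus",
#'                 ref = "Vmn1r30", hit_score = c(5, 9))
#' annotateTranscripts(h)$annotation
#' @export
annotateTranscripts <- function(hits) {
  hits$annotation <- hits$ref
  key <- paste(hits$species, hits$ref, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ord <- idx[order(-hits$hit_score[idx], hits$id[idx])]
    hits$annotation[ord] <- paste0(hits$ref[ord], ".",
                                   seq_along(ord))
  }
  hits
}

.rootGeneTree <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup) && all(outgroup %in% tree$tip.label))
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE))
  if (ape::is.rooted(tree)) return(tree)
  warning("gene tree unrooted and no outgroup supplied; midpoint-rooting")
  phangorn::midpoint(tree)
}

.collapseLowSupport <- function(tree, minSupport) {
  if (is.null(tree$node.label) || is.na(minSupport)) return(tree)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  low <- which(!is.na(sup) & sup < minSupport)
  if (!length(low)) return(tree)
  # contract low-support internal edges via zero-length collapse
  t2 <- tree
  if (is.null(t2$edge.length)) t2$edge.length <- rep(1, nrow(t2$edge))
  for (nd in low + ntip) {
    e <- which(t2$edge[, 2] == nd)
    if (length(e)) t2$edge.length[e] <- 0
  }
  ape::di2multi(t2, tol = 1e-12)
}

#' Delimit orthogroups on a gene tree by species-overlap reconciliation
#'
#' Formalises the rule that the receptor phylogeny should recapitulate the
#' species phylogeny: an internal node is a duplication node iff the
#' species sets of its children overlap; a duplication node is \emph{local}
#' iff its whole subtree spans a single species (a within-species tandem
#' array). Orthogroups are the maximal subtrees containing no non-local
#' duplication node, so every leaf belongs to exactly one orthogroup.
#' Multifurcations (e.g. from collapsing low-support edges) are treated
#' conservatively: no duplication is inferred across a polytomy.
#'
#' @param tree gene tree (\code{phylo}); rooted with \code{outgroup} if
#'   given, else midpoint-rooted with a warning when unrooted
#' @param leafInfo data.frame with columns \code{label}, \code{species} and
#'   optionally \code{refGene} (NA for non-reference leaves)
#' @param outgroup optional outgroup tip label(s) for rooting
#' @param minSupport collapse internal edges with bootstrap support below
#'   this value before reconciliation (NA to disable; default 50)
#' @param referenceSpecies species name of the reference repertoire
#' @return an \code{\linkS4class{OrthogroupSet}} (names and clades are
#'   filled by \code{\link{nameOrthogroups}})
#' @export
delimitOrthogroups <- function(tree, leafInfo, outgroup = NULL,
                               minSupport = 50,
                               referenceSpecies = "domesticus") {
  if (is.null(leafInfo$refGene)) leafInfo$refGene <- NA_character_
  missing <- setdiff(tree$tip.label, leafInfo$label)
  if (length(missing))
    stop("leafInfo lacks entries for: ", paste(missing, collapse = ", "))
  tree <- .rootGeneTree(tree, outgroup)
  tree <- .collapseLowSupport(tree, minSupport)
  ntip <- length(tree$tip.label)
  spOf <- stats::setNames(leafInfo$species, leafInfo$label)
  nodes <- ntip + seq_len(tree$Nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])

  spSet <- vector("list", ntip + tree$Nnode)
  isDup <- logical(ntip + tree$Nnode)
  clean <- logical(ntip + tree$Nnode)
  po <- .postorderNodes(tree)
  for (v in po) {
    if (v <= ntip) {
      spSet[[v]] <- spOf[[tree$tip.label[v]]]
      clean[v] <- TRUE
      next
    }
    ch <- kids[[as.character(v)]]
    sets <- spSet[ch]
    spSet[[v]] <- unique(unlist(sets))
    overlap <- FALSE
    if (length(ch) == 2L) {
      overlap <- length(intersect(sets[[1]], sets[[2]])) > 0L
    }  # polytomy: conservatively no duplication
    local <- length(spSet[[v]]) == 1L
    isDup[v] <- overlap
    clean[v] <- all(clean[ch]) && !(overlap && !local)
  }

  groups <- list()
  assign <- function(v) {
    if (clean[v]) {
      leaves <- if (v <= ntip) tree$tip.label[v]
      else tree$tip.label[.descendantTips(tree, v)]
      groups[[length(groups) + 1L]] <<- leaves
    } else {
      for (ch in kids[[as.character(v)]]) assign(ch)
    }
  }
  assign(ntip + 1L)

  tab <- data.frame(name = paste0("OG", seq_along(groups)),
                    n_members = lengths(groups),
                    n_species = NA_integer_, species_set = NA_character_,
                    reference_genes = NA_character_,
                    category = NA_character_, clade = NA_character_,
                    stringsAsFactors = FALSE)
  refOf <- stats::setNames(leafInfo$refGene, leafInfo$label)
  for (i in seq_along(groups)) {
    sp <- unique(unname(spOf[groups[[i]]]))
    refs <- unique(stats::na.omit(unname(refOf[groups[[i]]])))
    tab$n_species[i] <- length(sp)
    tab$species_set[i] <- paste(sort(sp), collapse = ",")
    tab$reference_genes[i] <- paste(sort(refs), collapse = ",")
  }
  ogs <- new("OrthogroupSet", table = tab,
             members = stats::setNames(groups, tab$name))
  categorizeOrthogroups(ogs, referenceSpecies = referenceSpecies)
}

.postorderNodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- integer(0)
  stack <- root
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    if (v > ntip)
      stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  rev(seen)
}

.descendantTips <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x <= ntip) out <- c(out, x)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == x, 2])
  }
  sort(out)
}

#' Assign orthology categories
#'
#' \code{reference_only}: only the reference species;
#' \code{non_orthologous}: a single non-reference species;
#' \code{low_orthology}: 2-3 species; \code{high_orthology}: 4-6 species.
#' The reference counts as one of the six species, so the four categories
#' partition all orthogroups.
#'
#' @param ogs an \code{\linkS4class{OrthogroupSet}}
#' @param referenceSpecies name of the reference species
#' @return the \code{OrthogroupSet} with \code{category} filled
#' @export
categorizeOrthogroups <- function(ogs, referenceSpecies = "domesticus") {
  tab <- ogs@table
  for (i in seq_len(nrow(tab))) {
    sp <- strsplit(tab$species_set[i], ",", fixed = TRUE)[[1]]
    n <- length(sp)
    tab$category[i] <-
      if (n == 1L && identical(sp, referenceSpecies)) "reference_only"
      else if (n == 1L) "non_orthologous"
      else if (n <= 3L) "low_orthology"
      else "high_orthology"
  }
  ogs@table <- tab
  ogs
}

# numeric part of a reference gene id = its trailing digit run
# (Vmn1r25 -> 25, V1rd19 -> 19); NA when there is none
.refIdNum <- function(ids) {
  ids <- sub("\\.\\d+$", "", ids)  # strip variant suffixes first
  m <- regmatches(ids, regexpr("\\d+$", ids))
  out <- rep(NA_real_, length(ids))
  out[regexpr("\\d+$", ids) > 0] <- as.numeric(m)
  out
}

.combinationId <- function(refs) {
  num <- .refIdNum(refs)
  o <- order(num, refs)
  refs <- refs[o]; num <- num[o]
  pre <- sub("\\d+$", "", refs)
  if (length(unique(pre)) == 1L && !any(is.na(num)))
    paste0(pre[1], paste(num, collapse = "/"))
  else paste(refs, collapse = "/")
}

#' Name orthogroups with the reference annotation grammar
#'
#' One reference gene: its id. Two or more: a combination-ID joining the
#' numeric parts in ascending order (\code{Vmn1r25/30}). No reference
#' gene: the ids of the reference genes in the nearest enclosing subtree
#' the group is basal to are collected; three or fewer give a
#' combination-ID, more give \code{basal<lowest id>}. Groups in trees with
#' no reference leaves at all keep their positional \code{OG<i>} name.
#'
#' @param ogs an \code{\linkS4class{OrthogroupSet}} from
#'   \code{\link{delimitOrthogroups}}
#' @param tree the (rooted) gene tree used for delimitation
#' @param leafInfo the leaf table used for delimitation
#' @return the \code{OrthogroupSet} with \code{name} replaced by grammar
#'   names (made unique with \code{_b2}, \code{_b3} suffixes on repeats)
#' @export
nameOrthogroups <- function(ogs, tree, leafInfo) {
  tree <- .rootGeneTree(tree)
  refOf <- stats::setNames(leafInfo$refGene, leafInfo$label)
  ntip <- length(tree$tip.label)
  parentOf <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
  tab <- ogs@table
  for (i in seq_len(nrow(tab))) {
    refs <- unique(stats::na.omit(unname(refOf[ogs@members[[i]]])))
    if (length(refs) == 1L) { tab$name[i] <- refs; next }
    if (length(refs) >= 2L) { tab$name[i] <- .combinationId(refs); next }
    # basal group: walk up to the nearest ancestor whose subtree holds
    # reference genes
    mrca <- if (length(ogs@members[[i]]) == 1L)
      match(ogs@members[[i]], tree$tip.label)
    else ape::getMRCA(tree, ogs@members[[i]])
    v <- mrca
    basalRefs <- character()
    while (as.character(v) %in% names(parentOf)) {
      v <- parentOf[[as.character(v)]]
      tips <- tree$tip.label[.descendantTips(tree, v)]
      basalRefs <- unique(stats::na.omit(unname(refOf[tips])))
      if (length(basalRefs)) break
    }
    if (!length(basalRefs)) next  # no reference anywhere: keep OG<i>
    if (length(basalRefs) <= 3L) {
      tab$name[i] <- .combinationId(basalRefs)
    } else {
      num <- .refIdNum(basalRefs)
      tab$name[i] <- paste0("basal", basalRefs[order(num,
                                                     basalRefs)][1])
    }
  }
  if (anyDuplicated(tab$name)) {
    for (nm in unique(tab$name[duplicated(tab$name)])) {
      idx <- which(tab$name == nm)
      tab$name[idx[-1]] <- paste0(nm, "_b", seq_along(idx[-1]) + 1L)
    }
  }
  names(ogs@members) <- tab$name
  ogs@table <- tab
  ogs
}

#' Attach clade labels to orthogroups
#'
#' Orthogroups inherit the clade of their member reference genes (modal
#' clade on conflict). Groups without reference members inherit the modal
#' clade of the reference genes in the nearest reference-containing
#' ancestor subtree of the gene tree; groups that cannot be placed get
#' \code{"unplaced"}.
#'
#' @param ogs an \code{\linkS4class{OrthogroupSet}}
#' @param cladeMap named character vector: reference gene id -> clade
#' @param tree,leafInfo the gene tree and leaf table (needed only for
#'   reference-free groups)
#' @return the \code{OrthogroupSet} with \code{clade} filled
#' @export
assignClades <- function(ogs, cladeMap, tree = NULL, leafInfo = NULL) {
  tab <- ogs@table
  modal <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  refOf <- if (!is.null(leafInfo))
    stats::setNames(leafInfo$refGene, leafInfo$label) else NULL
  if (!is.null(tree)) {
    tree <- .rootGeneTree(tree)
    parentOf <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
  }
  for (i in seq_len(nrow(tab))) {
    refs <- strsplit(tab$reference_genes[i], ",", fixed = TRUE)[[1]]
    refs <- refs[nzchar(refs)]
    if (length(refs)) {
      tab$clade[i] <- modal(unname(cladeMap[refs]))
      next
    }
    if (is.null(tree) || is.null(refOf)) { tab$clade[i] <- "unplaced"; next }
    mrca <- if (length(ogs@members[[i]]) == 1L)
      match(ogs@members[[i]], tree$tip.label)
    else ape::getMRCA(tree, ogs@members[[i]])
    v <- mrca
    clade <- NA_character_
    while (as.character(v) %in% names(parentOf)) {
      v <- parentOf[[as.character(v)]]
      tips <- tree$tip.label[.descendantTips(tree, v)]
      nearRefs <- unique(stats::na.omit(unname(refOf[tips])))
      if (length(nearRefs)) {
        clade <- modal(unname(cladeMap[nearRefs]))
        break
      }
    }
    tab$clade[i] <- if (is.na(clade)) "unplaced" else clade
  }
  tab$clade[is.na(tab$clade)] <- "unplaced"
  ogs@table <- tab
  ogs
}

#' Build a gene tree from peptides by distance methods
#'
#' A deliberately simple neighbour-joining builder for synthetic tests and
#' desk-scale runs: center-star alignment, pairwise identity distances
#' (1 - identity/100), NJ, midpoint rooting. Externally inferred
#' maximum-likelihood trees should be supplied to
#' \code{\link{delimitOrthogroups}} whenever available.
#'
#' @param peptides named character vector or \code{AAStringSet}
#' @param msa optional precomputed alignment
#' @param collapseTol internal edges shorter than this are collapsed into
#'   polytomies before rooting; the default of half an amino acid change
#'   per alignment column treats edges supported by less than one
#'   substitution as unresolved, which the species-overlap delimiter then
#'   handles conservatively. Set 0 to keep the raw binary tree.
#' @return rooted \code{phylo}
#' @export
buildGeneTree <- function(peptides, msa = NULL, collapseTol = NULL) {
  if (inherits(peptides, "AAStringSet")) {
    nm <- names(peptides)
    peptides <- as.character(peptides)
    names(peptides) <- nm
  }
  if (length(peptides) < 3L)
    stop("need at least 3 sequences to build a tree")
  if (is.null(msa)) msa <- centerStarAlign(peptides)
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idy <- .alignmentIdentity(msa[[i]], msa[[j]])$identity
    d[i, j] <- d[j, i] <- 1 - idy / 100
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (is.null(collapseTol)) collapseTol <- 0.5 / nchar(msa[[1]])
  if (collapseTol > 0) tr <- ape::di2multi(tr, tol = collapseTol)
  phangorn::midpoint(tr)
}
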