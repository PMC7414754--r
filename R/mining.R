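#' Extract open reading frames under a receptor gene model
#'
#' Scans both strands and all three frames of every input record for ORFs
#' satisfying the gene model. ORF length is counted in codons of the
#' encoded peptide (initiator included, terminator excluded). By default
#' only the longest qualifying ORF per input record is kept. Coordinates
#' are 0-based half-open on the reported strand and cover the coding codons
#' only.
#'
#' @param raw named character vector or \code{DNAStringSet} of transcript
#'   sequences over A/C/G/T/N
#' @param model a \code{\linkS4class{GeneModel}}
#' @param longestOnly keep only the longest qualifying ORF per record
#' @param species species identifier attached to the output (default:
#'   parsed from ids of the form \code{species|...}, else NA)
#' @return data.frame with columns id, species, cds, peptide, strand,
#'   start, end, source; zero rows when nothing qualifies
#' @examples
#' gm <- GeneModel(minLen = 3, maxLen = 10)
#' extractOrfs(c(x = "AAATGGCTGCTGCATGATT"), gm)
#' @export
extractOrfs <- function(raw, model = GeneModel(), longestOnly = TRUE,
                        species = NULL) {
  if (inherits(raw, "DNAStringSet")) {
    nm <- names(raw)
    raw <- as.character(raw)
    names(raw) <- nm
  }
  if (is.null(names(raw)))
    names(raw) <- paste0("seq", seq_along(raw))
  rows <- list()
  for (id in names(raw)) {
    orfs <- .orfScan(toupper(raw[[id]]), model)
    if (!nrow(orfs)) next
    if (longestOnly) {
      orfs <- orfs[order(-orfs$codons, orfs$strand, orfs$start), ,
                   drop = FALSE]
      orfs <- orfs[1, , drop = FALSE]
    }
    sp <- if (!is.null(species)) species
    else if (grepl("|", id, fixed = TRUE)) strsplit(id, "|",
                                                    fixed = TRUE)[[1]][1]
    else NA_character_
    for (k in seq_len(nrow(orfs))) {
      suffix <- if (nrow(orfs) > 1L) paste0(".orf", k) else ""
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(id, suffix), species = sp, cds = orfs$cds[k],
        peptide = orfs$peptide[k], strand = orfs$strand[k],
        start = orfs$start[k], end = orfs$end[k], source = "assembled",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(id = character(), species = character(),
                      cds = character(), peptide = character(),
                      strand = character(), start = integer(),
                      end = integer(), source = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# All qualifying ORFs in the six frames of one sequence.
.orfScan <- function(seq, model) {
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revComp(seq)
    n <- nchar(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 1L) next
      cods <- substring(s, frame + 3L * seq_len(ncod) - 2L,
                        frame + 3L * seq_len(ncod))
      aa <- ifelse(cods %in% names(.codonTable$aa),
                   .codonTable$aa[cods], "X")
      isStop <- cods %in% .STOP_CODONS
      # segment boundaries between stops
      segStart <- c(1L, which(isStop) + 1L)
      segEnd <- c(which(isStop) - 1L, ncod)
      for (si in seq_along(segStart)) {
        a <- segStart[si]; b <- segEnd[si]
        if (a > b) next
        hasStop <- b < ncod && isStop[b + 1L]
        if (model@requireStop && !hasStop) next
        if (model@requireStart) {
          starts <- which(aa[a:b] == "M")
          if (!length(starts)) next
          a <- a + starts[1L] - 1L  # longest ORF in segment: first ATG
        }
        len <- b - a + 1L
        if (len < model@minLen || len > model@maxLen) next
        if (any(aa[a:b] == "X")) next
        cds <- paste(cods[a:b], collapse = "")
        start0 <- frame + 3L * (a - 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          cds = cds, peptide = paste(aa[a:b], collapse = ""),
          strand = strand, start = start0, end = start0 + 3L * len,
          codons = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(cds = character(), peptide = character(),
                      strand = character(), start = integer(),
                      end = integer(), codons = integer()))
  do.call(rbind, hits)
}

.revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Remove exact-duplicate and contained coding sequences
#'
#' Drops any sequence identical to, or an exact substring of, another
#' retained sequence, on either strand. The longest member of each
#' containment chain is kept; among equal candidates the lexicographically
#' smallest id wins.
#'
#' @param cds named character vector or \code{DNAStringSet} of DNA
#'   sequences
#' @return named character vector of retained sequences
#' @examples
#' dedupeTranscripts(c(a = "ATGGCCTGA", b = "GGCC"))
#' @export
dedupeTranscripts <- function(cds) {
  if (inherits(cds, "DNAStringSet")) {
    nm <- names(cds)
    cds <- as.character(cds)
    names(cds) <- nm
  }
  if (length(cds) <= 1L) return(cds)
  ord <- order(-nchar(cds), names(cds))
  kept <- character()
  keptIds <- character()
  for (i in ord) {
    s <- cds[[i]]
    rc <- .revComp(s)
    contained <- any(vapply(kept, function(k)
      grepl(s, k, fixed = TRUE) || grepl(rc, k, fixed = TRUE), logical(1)))
    if (!contained) {
      kept <- c(kept, s)
      keptIds <- c(keptIds, names(cds)[i])
    }
  }
  out <- kept
  names(out) <- keptIds
  out[order(match(keptIds, names(cds)))]
}

#' Filter candidate receptors by identity with the species' receptor group
#'
#' Aligns the species' candidate peptides (center-star progressive
#' alignment, or a supplied alignment) and drops every sequence whose mean
#' pairwise identity against all others falls below the threshold. Identity
#' is matches over aligned columns, excluding columns where both rows are
#' gapped and excluding terminal gap overhangs. A single pass; survivors
#' are not re-examined.
#'
#' @param peptides named character vector or \code{AAStringSet} of one
#'   species' candidate peptides
#' @param threshold percent identity cutoff (default 30)
#' @param stat \code{"mean"} (default) or \code{"min"} pairwise identity
#' @param msa optional precomputed alignment (named gapped rows covering
#'   \code{names(peptides)})
#' @return list with \code{retained}, \code{dropped} (named character
#'   vectors of input peptides) and \code{identity} (named numeric vector
#'   of the statistic per sequence)
#' @export
identityFilter <- function(peptides, threshold = 30,
                           stat = c("mean", "min"), msa = NULL) {
  stat <- match.arg(stat)
  if (inherits(peptides, "AAStringSet")) {
    nm <- names(peptides)
    peptides <- as.character(peptides)
    names(peptides) <- nm
  }
  if (length(peptides) < 2L) {
    warning("identityFilter: fewer than 2 sequences; returned unchanged")
    return(list(retained = peptides,
                dropped = peptides[0],
                identity = stats::setNames(rep(NA_real_,
                                               length(peptides)),
                                           names(peptides))))
  }
  if (is.null(msa)) msa <- centerStarAlign(peptides)
  msa <- msa[names(peptides)]
  n <- length(msa)
  idm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idm[i, j] <- idm[j, i] <-
      .alignmentIdentity(msa[[i]], msa[[j]])$identity
  }
  val <- if (stat == "mean") rowMeans(idm, na.rm = TRUE)
  else apply(idm, 1, min, na.rm = TRUE)
  names(val) <- names(peptides)
  keep <- val >= threshold
  list(retained = peptides[keep], dropped = peptides[!keep],
       identity = val)
}

#' Mine candidate receptors from one species' transcripts
#'
#' The fixed recovery pipeline: ORF extraction under the gene model,
#' exact/containment deduplication, translation, best-hit annotation
#' against the reference repertoire, and the group-identity filter.
#'
#' @param raw transcript DNA sequences (named character or
#'   \code{DNAStringSet})
#' @param referencePeptides named reference peptides for best-hit
#'   annotation
#' @param model a \code{\linkS4class{GeneModel}}
#' @param threshold identity-filter cutoff percent
#' @param species species identifier for the output table
#' @param externalHits optional data.frame (query, ref, score, identity)
#'   from \code{\link{readBlastHits}} used instead of internal scoring
#' @return data.frame of retained transcripts with best-hit annotation
#'   columns (ref, hit_score, hit_identity)
#' @export
mineReceptors <- function(raw, referencePeptides, model = GeneModel(),
                          threshold = 30, species = NULL,
                          externalHits = NULL) {
  orfs <- extractOrfs(raw, model, species = species)
  if (!nrow(orfs)) return(orfs)
  cds <- stats::setNames(orfs$cds, orfs$id)
  kept <- dedupeTranscripts(cds)
  orfs <- orfs[orfs$id %in% names(kept), , drop = FALSE]
  if (nrow(orfs) >= 2L) {
    flt <- identityFilter(stats::setNames(orfs$peptide, orfs$id),
                          threshold = threshold)
    orfs <- orfs[orfs$id %in% names(flt$retained), , drop = FALSE]
  }
  if (!is.null(externalHits)) {
    m <- match(orfs$id, externalHits$query)
    orfs$ref <- externalHits$ref[m]
    orfs$hit_score <- externalHits$score[m]
    orfs$hit_identity <- externalHits$identity[m]
  } else {
    hits <- lapply(orfs$peptide, bestReferenceHit,
                   reference = referencePeptides)
    orfs$ref <- vapply(hits, `[[`, character(1), "ref")
    orfs$hit_score <- vapply(hits, `[[`, numeric(1), "score")
    orfs$hit_identity <- vapply(hits, `[[`, numeric(1), "identity")
  }
  orfs
}
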