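#' Classify a pair of same-annotation transcripts as variant or duplicate
#'
#' The four variant rules are checked in order on the global pairwise
#' peptide alignment: (1) identical peptides; (2) truncation, i.e. the
#' shorter ungapped peptide is at most \code{truncFrac} times the longer;
#' (3) all variation within \code{endWindow} columns of either alignment
#' terminus; (4) all remaining variation within \code{gapWindow} columns of
#' a gap column. A mismatch column is \emph{central} iff it is more than
#' \code{endWindow} columns from both termini and more than
#' \code{gapWindow} columns from every gap column; the pair is a putative
#' gene duplicate iff at least one central mismatch survives all four
#' variant rules.
#'
#' @param aln a pairwise alignment from \code{\link{pairwiseAlignPeptides}}
#' @param endWindow terminal window E in columns (default 10)
#' @param gapWindow gap-proximity window G in columns (default 5)
#' @param truncFrac ungapped-length ratio at or below which the truncation
#'   rule fires (default 0.75)
#' @return list(verdict, rule, endWindow, gapWindow, truncFrac) where
#'   verdict is \code{transcript_variant} or \code{gene_duplicate} and rule
#'   is one of same_peptide, truncation, end_variation, gap_adjacent,
#'   central_change
#' @examples
#' aln <- pairwiseAlignPeptides("MKLLVNTewk", "MKLLVNTewk")
#' classifyPair(aln)$rule
#' @export
classifyPair <- function(aln, endWindow = 10, gapWindow = 5,
                         truncFrac = 0.75) {
  a <- gsub("-", "", aln$alignedA, fixed = TRUE)
  b <- gsub("-", "", aln$alignedB, fixed = TRUE)
  out <- function(verdict, rule)
    list(verdict = verdict, rule = rule, endWindow = endWindow,
         gapWindow = gapWindow, truncFrac = truncFrac)
  if (identical(a, b)) return(out("transcript_variant", "same_peptide"))
  lens <- c(nchar(a), nchar(b))
  if (min(lens) <= truncFrac * max(lens))
    return(out("transcript_variant", "truncation"))
  ca <- strsplit(aln$alignedA, "")[[1]]
  cb <- strsplit(aln$alignedB, "")[[1]]
  L <- length(ca)
  gap <- ca == "-" | cb == "-"
  mism <- !gap & ca != cb
  varCols <- which(gap | mism)
  nearEnd <- function(i) i <= endWindow | i > L - endWindow
  gapIdx <- which(gap)
  nearGap <- function(i) {
    if (!length(gapIdx)) return(rep(FALSE, length(i)))
    vapply(i, function(k) any(abs(gapIdx - k) <= gapWindow), logical(1))
  }
  mIdx <- which(mism)
  central <- mIdx[!nearEnd(mIdx) & !nearGap(mIdx)]
  if (length(central)) return(out("gene_duplicate", "central_change"))
  if (all(nearEnd(varCols)))
    return(out("transcript_variant", "end_variation"))
  out("transcript_variant", "gap_adjacent")
}

#' Classify all same-species members of an orthogroup
#'
#' Within one orthogroup and one species, the member with the longest
#' peptide (ties by lexicographically smallest id) is the unclassified
#' primary; every other member is aligned to its highest-scoring
#' same-species partner and classified with \code{\link{classifyPair}}.
#' Duplications within orthogroups are treated independently per species.
#'
#' @param peptides named character vector of the same-species members'
#'   peptides (>= 1)
#' @param endWindow,gapWindow,truncFrac see \code{\link{classifyPair}}
#' @param alignParams scoring parameters for
#'   \code{\link{pairwiseAlignPeptides}}
#' @return data.frame (transcript, partner, verdict, rule, end_window,
#'   gap_window); zero rows for a singleton
#' @export
classifySpeciesSet <- function(peptides, endWindow = 10, gapWindow = 5,
                               truncFrac = 0.75,
                               alignParams = .needleDefaults()) {
  empty <- data.frame(transcript = character(), partner = character(),
                      verdict = character(), rule = character(),
                      end_window = numeric(), gap_window = numeric(),
                      stringsAsFactors = FALSE)
  if (length(peptides) < 2L) return(empty)
  ids <- names(peptides)
  primary <- ids[order(-nchar(peptides), ids)][1]
  alnCache <- list()
  alignOf <- function(i, j) {
    k <- paste(sort(c(i, j)), collapse = "\r")
    if (is.null(alnCache[[k]]))
      alnCache[[k]] <<- pairwiseAlignPeptides(peptides[[i]],
                                              peptides[[j]],
                                              alignParams)
    alnCache[[k]]
  }
  rows <- list()
  for (id in setdiff(ids, primary)) {
    partners <- setdiff(ids, id)
    scores <- vapply(partners, function(p) alignOf(id, p)$score,
                     numeric(1))
    best <- partners[order(-scores, partners)][1]
    aln <- alignOf(id, best)
    # classifyPair is symmetric in verdict; orient so A is this transcript
    cl <- classifyPair(aln, endWindow, gapWindow, truncFrac)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript = id, partner = best, verdict = cl$verdict,
      rule = cl$rule, end_window = endWindow, gap_window = gapWindow,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Summarise duplicate/variant calls per species (and optionally clade)
#'
#' @param calls data.frame from \code{\link{classifySpeciesSet}} with a
#'   \code{species} column (and optionally \code{clade})
#' @return data.frame of counts and fractions of duplicates and variants
#'   per grouping
#' @export
summarizeDupVar <- function(calls) {
  if (!nrow(calls))
    return(data.frame(species = character(), n_calls = integer(),
                      n_duplicates = integer(), n_variants = integer(),
                      pct_duplicates = numeric()))
  by <- intersect(c("species", "clade"), names(calls))
  key <- do.call(paste, c(calls[by], sep = "\r"))
  rows <- lapply(unique(key), function(k) {
    sub <- calls[key == k, , drop = FALSE]
    ndup <- sum(sub$verdict == "gene_duplicate")
    cbind(sub[1, by, drop = FALSE],
          data.frame(n_calls = nrow(sub), n_duplicates = ndup,
                     n_variants = nrow(sub) - ndup,
                     pct_duplicates = .roundHalfUp(100 * ndup / nrow(sub),
                                                   2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
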