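.needleDefaults <- function() {
  list(matrix = "BLOSUM62", gapOpen = 10, gapExtend = 0.5)
}

.substMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise peptide alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under the classic protein defaults
#' (BLOSUM62, gap open 10, gap extend 0.5; a gap of length L costs
#' open + L x extend). Identity is computed over aligned columns, excluding
#' terminal gap overhangs by default.
#'
#' @param a,b peptide strings (nonempty)
#' @param params list with elements \code{matrix}, \code{gapOpen},
#'   \code{gapExtend}
#' @param countEndGaps if TRUE the identity denominator includes terminal
#'   gap columns
#' @return list with \code{alignedA}, \code{alignedB} (equal-length gapped
#'   strings), \code{score}, \code{identity} (percent), \code{gapColumns}
#'   (1-based columns containing a gap)
#' @examples
#' pairwiseAlignPeptides("MKLV", "MLV")$identity
#' @export
pairwiseAlignPeptides <- function(a, b, params = .needleDefaults(),
                                  countEndGaps = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("empty peptide sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .substMatrix(params$matrix),
    gapOpening = params$gapOpen, gapExtension = params$gapExtend)
  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  stats <- .alignmentIdentity(alnA, alnB, countEndGaps = countEndGaps)
  list(alignedA = alnA, alignedB = alnB,
       score = Biostrings::score(pa),
       identity = stats$identity,
       gapColumns = stats$gapColumns)
}

# identity over aligned columns; dual-gap columns never occur in pairwise
# global alignments but are excluded anyway so the same routine serves MSA
# rows. Terminal gap runs (leading/trailing) excluded unless countEndGaps.
.alignmentIdentity <- function(alnA, alnB, countEndGaps = FALSE) {
  ca <- strsplit(alnA, "")[[1]]
  cb <- strsplit(alnB, "")[[1]]
  stopifnot(length(ca) == length(cb))
  gapA <- ca == "-"
  gapB <- cb == "-"
  keep <- !(gapA & gapB)
  if (!countEndGaps) {
    ng <- which(!(gapA | gapB))
    if (length(ng)) {
      keep[seq_along(keep) < ng[1]] <- FALSE
      keep[seq_along(keep) > ng[length(ng)]] <- FALSE
    } else keep[] <- FALSE
  }
  n <- sum(keep)
  matches <- sum(keep & ca == cb & !gapA)
  list(identity = if (n > 0) 100 * matches / n else 0,
       gapColumns = which((gapA | gapB) & !(gapA & gapB)),
       columns = n)
}

#' Local best-hit scoring of a query peptide against a reference repertoire
#'
#' Smith-Waterman local alignment of the query against every reference
#' peptide (BLOSUM62, affine gaps), returning the reference maximising the
#' score. Ties are broken by higher percent identity, then by the
#' lexicographically smaller reference id.
#'
#' @param query peptide string
#' @param reference named character vector (or \code{AAStringSet}) of
#'   reference peptides; names are reference gene ids
#' @param params scoring parameters as in
#'   \code{\link{pairwiseAlignPeptides}}
#' @return list(ref, score, identity)
#' @export
bestReferenceHit <- function(query, reference, params = .needleDefaults()) {
  if (inherits(reference, "AAStringSet")) {
    nm <- names(reference)
    reference <- as.character(reference)
    names(reference) <- nm
  }
  if (length(reference) == 0L)
    stop("bestReferenceHit: empty reference repertoire")
  mat <- .substMatrix(params$matrix)
  best <- NULL
  for (id in names(reference)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(reference[[id]]),
      type = "local", substitutionMatrix = mat,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend)
    sc <- Biostrings::score(pa)
    idy <- .alignmentIdentity(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)),
      countEndGaps = TRUE)$identity
    cand <- list(ref = id, score = sc, identity = idy)
    if (is.null(best) ||
        sc > best$score ||
        (sc == best$score && idy > best$identity) ||
        (sc == best$score && idy == best$identity && id < best$ref))
      best <- cand
  }
  best
}

#' Read blast tabular (outfmt 6) hits and reduce to best hit per query
#'
#' Accepts the 12-column blast tabular dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). The best hit
#' per query is the row with the highest bitscore, ties broken by higher
#' pident then lexicographically smaller sseqid.
#'
#' @param path path to a tab-delimited hit file without header
#' @return data.frame (query, ref, score, identity), one row per query
#' @export
readBlastHits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) != 12L) stop("expected 12 blast tabular columns, got ",
                           ncol(x))
  names(x) <- cols
  x <- x[order(x$qseqid, -x$bitscore, -x$pident, x$sseqid), ]
  x <- x[!duplicated(x$qseqid), ]
  data.frame(query = x$qseqid, ref = x$sseqid, score = x$bitscore,
             identity = x$pident, stringsAsFactors = FALSE)
}

#' Center-star progressive multiple alignment
#'
#' Picks the center sequence maximising the summed global alignment score
#' to all others, aligns every sequence to the center, and merges the
#' pairwise alignments by taking the union of center-gap insertions. A
#' desk-scale progressive aligner adequate for within-family receptor
#' peptides; externally computed alignment FASTA can be supplied anywhere
#' the package takes an MSA.
#'
#' @param seqs named character vector or \code{AAStringSet} of peptides
#' @param params scoring parameters as in
#'   \code{\link{pairwiseAlignPeptides}}
#' @return named character vector of equal-length gapped rows
#' @export
centerStarAlign <- function(seqs, params = .needleDefaults()) {
  if (inherits(seqs, "AAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  n <- length(seqs)
  if (n == 0L) return(character())
  if (n == 1L) return(seqs)
  ids <- names(seqs)
  mat <- .substMatrix(params$matrix)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
      type = "global", substitutionMatrix = mat,
      gapOpening = params$gapOpen, gapExtension = params$gapExtend,
      scoreOnly = TRUE)
    score[i, j] <- score[j, i] <- s
  }
  center <- which.max(rowSums(score))
  others <- setdiff(seq_len(n), center)
  Lc <- nchar(seqs[[center]])
  alns <- list()
  # insertion profile per alignment: integer vector indexed by anchor p
  # (0..Lc = number of center residues already consumed) -> run length
  insProfile <- function(centerAln) {
    ins <- integer(Lc + 1L)
    p <- 0L
    for (ch in strsplit(centerAln, "")[[1]]) {
      if (ch == "-") ins[p + 1L] <- ins[p + 1L] + 1L else p <- p + 1L
    }
    ins
  }
  master <- integer(Lc + 1L)
  for (i in others) {
    alns[[as.character(i)]] <- pairwiseAlignPeptides(seqs[[center]],
                                                     seqs[[i]], params)
    master <- pmax(master, insProfile(alns[[as.character(i)]]$alignedA))
  }
  buildRow <- function(centerAln, subjectAln) {
    cs <- strsplit(centerAln, "")[[1]]
    ss <- strsplit(subjectAln, "")[[1]]
    out <- character()
    i <- 1L
    for (p in 0:Lc) {
      run <- character()
      while (i <= length(cs) && cs[i] == "-") {
        run <- c(run, ss[i])
        i <- i + 1L
      }
      out <- c(out, run, rep("-", master[p + 1L] - length(run)))
      if (p < Lc) {  # the next center residue
        out <- c(out, ss[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }
  centerChars <- strsplit(seqs[[center]], "")[[1]]
  centerRow <- paste(unlist(lapply(0:Lc, function(p) {
    c(rep("-", master[p + 1L]),
      if (p < Lc) centerChars[p + 1L] else character())
  })), collapse = "")
  result <- character(n)
  names(result) <- ids
  result[center] <- centerRow
  for (i in others)
    result[i] <- buildRow(alns[[as.character(i)]]$alignedA,
                          alns[[as.character(i)]]$alignedB)
  result
}
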