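#' Classify variable alignment columns into site categories
#'
#' Works on an alignment with one representative peptide per species
#' (sequences shorter than \code{shortLenFrac} of the median ungapped
#' length, i.e. short transcript variants, are excluded first; all-gap
#' columns are removed). For each variable column the consensus is the
#' majority residue (ties resolved toward the reference species' residue,
#' else alphabetically); with k = species deviating from consensus and
#' d = distinct deviant residues the category is:
#' \code{single_species} (k = 1), \code{two_species_distinct} (k = 2,
#' d = 2), \code{shared_2_3} (2 <= k <= 3, d = 1), \code{highly_variable}
#' (k >= 4, or d >= 3, or k = 3 with d = 2). The (k, d) map is total and
#' disjoint, so every
#' variable column gets exactly one category. Gapped residues do not count
#' as deviations; a column needs at least two ungapped species to be
#' assessed.
#'
#' @param msa named character vector or \code{AAStringSet} of aligned rows,
#'   one per species
#' @param referenceSpecies species used to resolve consensus ties
#' @param shortLenFrac exclude sequences with ungapped length below this
#'   fraction of the median (default 0.8)
#' @return data.frame (column, consensus, k, d, category) with 0-based
#'   column indices on the cleaned alignment; attribute
#'   \code{"kept_species"} lists the rows used
#' @export
classifySites <- function(msa, referenceSpecies = "domesticus",
                          shortLenFrac = 0.8) {
  if (inherits(msa, "AAStringSet")) {
    nm <- names(msa)
    msa <- as.character(msa)
    names(msa) <- nm
  }
  if (length(msa) < 2L) stop("need at least 2 species in the alignment")
  ungapped <- nchar(gsub("-", "", msa, fixed = TRUE))
  keep <- ungapped >= shortLenFrac * stats::median(ungapped)
  msa <- msa[keep]
  if (length(msa) < 2L)
    stop("fewer than 2 species remain after short-variant exclusion")
  mat <- do.call(rbind, strsplit(msa, ""))
  rownames(mat) <- names(msa)
  allGap <- apply(mat, 2, function(col) all(col == "-"))
  mat <- mat[, !allGap, drop = FALSE]
  rows <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (length(res) < 2L) next
    cnt <- table(res)
    topN <- max(cnt)
    tied <- names(cnt)[cnt == topN]
    consensus <- if (length(tied) == 1L) tied
    else if (referenceSpecies %in% names(col) &&
             col[referenceSpecies] %in% tied) col[[referenceSpecies]]
    else sort(tied)[1]
    dev <- res[res != consensus]
    k <- length(dev)
    if (k == 0L) next  # invariant column
    d <- length(unique(dev))
    category <- .siteCategory(k, d)
    rows[[length(rows) + 1L]] <- data.frame(
      column = j - 1L, consensus = consensus, k = k, d = d,
      category = category, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(column = integer(), consensus = character(),
                  k = integer(), d = integer(), category = character(),
                  stringsAsFactors = FALSE)
  attr(out, "kept_species") <- names(msa)
  out
}

# the declared (k, d) formalisation of the four site categories; k = 3
# with two distinct deviant residues counts as highly variable so the map
# is total over every 2-6 species column
.siteCategory <- function(k, d) {
  if (k >= 4L || d >= 3L || (k >= 3L && d >= 2L)) "highly_variable"
  else if (k == 1L) "single_species"
  else if (k == 2L && d == 2L) "two_species_distinct"
  else "shared_2_3"  # 2 <= k <= 3, d = 1
}

# Kyte-Doolittle hydropathy values
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' Assign membrane regions to a receptor peptide
#'
#' Uses an externally predicted per-residue topology when supplied;
#' otherwise a hydropathy heuristic stands in for an HMM predictor:
#' Kyte-Doolittle window of 19 residues, threshold 1.6; every
#' above-threshold window centre contributes its full 19-residue window,
#' overlapping windows are merged, and merged segments shorter than 15
#' residues are discarded. The topology is threaded from an extracellular
#' N-terminus (V1Rs have a short extracellular N-terminal region), so
#' loops alternate extracellular/intracellular between transmembrane
#' segments.
#'
#' @param peptide peptide string without stops
#' @param external optional data.frame (position 1-based, region) covering
#'   every residue, echoed back with \code{source = "external_table"}
#' @param window,threshold,minSegment hydropathy stand-in parameters
#' @return list(regions = character vector of per-residue labels in
#'   \{extracellular, transmembrane, intracellular\}, segments =
#'   data.frame(start, end), source)
#' @export
assignRegions <- function(peptide, external = NULL, window = 19L,
                          threshold = 1.6, minSegment = 15L) {
  L <- nchar(peptide)
  if (!is.null(external)) {
    if (nrow(external) != L || !setequal(external$position, seq_len(L)))
      stop("external topology table must cover every residue")
    reg <- external$region[order(external$position)]
    seg <- .segmentsOf(reg == "transmembrane")
    return(list(regions = reg, segments = seg,
                source = "external_table"))
  }
  aa <- strsplit(peptide, "")[[1]]
  h <- unname(.KD[aa])
  h[is.na(h)] <- 0
  half <- (window - 1L) %/% 2L
  tm <- rep(FALSE, L)
  if (L >= window) {
    means <- vapply(seq.int(half + 1L, L - half), function(i)
      mean(h[(i - half):(i + half)]), numeric(1))
    centers <- which(means > threshold) + half
    for (c0 in centers)
      tm[max(1L, c0 - half):min(L, c0 + half)] <- TRUE
  }
  seg <- .segmentsOf(tm)
  seg <- seg[seg$end - seg$start + 1L >= minSegment, , drop = FALSE]
  tm <- rep(FALSE, L)
  for (i in seq_len(nrow(seg))) tm[seg$start[i]:seg$end[i]] <- TRUE
  regions <- character(L)
  outside <- TRUE  # N-terminus is extracellular
  i <- 1L
  while (i <= L) {
    if (tm[i]) {
      j <- i
      while (j < L && tm[j + 1L]) j <- j + 1L
      regions[i:j] <- "transmembrane"
      outside <- !outside
      i <- j + 1L
    } else {
      regions[i] <- if (outside) "extracellular" else "intracellular"
      i <- i + 1L
    }
  }
  list(regions = regions, segments = seg, source = "hydropathy_standin")
}

.segmentsOf <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Tally variable sites by membrane region
#'
#' Maps every categorised alignment column to the region of the reference
#' species' residue in that column (columns where the reference is gapped
#' take the nearest ungapped reference residue to the left, or the first
#' residue when none exists) and tabulates counts per region per category
#' together with region-length-normalised densities.
#'
#' @param siteCategories data.frame from \code{\link{classifySites}}
#' @param refAligned the reference species' aligned (gapped) row on the
#'   same cleaned alignment
#' @param refRegions per-residue regions of the ungapped reference peptide
#'   from \code{\link{assignRegions}}
#' @return list(byRegion = data.frame(region, category, n),
#'   summary = data.frame(region, n_sites, fraction, region_length,
#'   density))
#' @export
regionChangeSummary <- function(siteCategories, refAligned, refRegions) {
  regionsAll <- c("extracellular", "transmembrane", "intracellular")
  cols <- strsplit(refAligned, "")[[1]]
  respos <- cumsum(cols != "-")
  colRegion <- function(j) {
    p <- respos[j + 1L]  # residues to the left of/at this 0-based column
    if (p == 0L) p <- 1L
    refRegions[p]
  }
  lenOf <- vapply(regionsAll, function(r) sum(refRegions == r),
                  numeric(1))
  if (!nrow(siteCategories)) {
    return(list(
      byRegion = data.frame(region = character(), category = character(),
                            n = integer()),
      summary = data.frame(region = regionsAll, n_sites = 0L,
                           fraction = 0, region_length = unname(lenOf),
                           density = 0)))
  }
  reg <- vapply(siteCategories$column, colRegion, character(1))
  byRegion <- as.data.frame(table(region = reg,
                                  category = siteCategories$category),
                            stringsAsFactors = FALSE)
  names(byRegion)[3] <- "n"
  tot <- nrow(siteCategories)
  nReg <- vapply(regionsAll, function(r) sum(reg == r), numeric(1))
  summary <- data.frame(
    region = regionsAll, n_sites = as.integer(nReg),
    fraction = nReg / tot, region_length = unname(lenOf),
    density = ifelse(lenOf > 0, nReg / lenOf, 0),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(byRegion = byRegion, summary = summary)
}
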