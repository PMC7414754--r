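# Codon-level machinery shared by the simulator and the dN/dS screen.
# All tables are built once at load time from Biostrings::GENETIC_CODE
# (standard code); stop codons are excluded from the sense-state space.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codonTable <- local({
  nt <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  all64 <- sort(all64)
  aa <- Biostrings::GENETIC_CODE[all64]
  list(codons = all64, aa = aa, sense = all64[!all64 %in% .STOP_CODONS])
})

.isTransition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# For every sense codon: the single-nucleotide neighbours, with position,
# transition flag, synonymous flag, and whether the target is a stop.
.codonNeighbours <- local({
  tab <- .codonTable
  nt <- c("A", "C", "G", "T")
  out <- vector("list", length(tab$sense))
  names(out) <- tab$sense
  for (cod in tab$sense) {
    chars <- strsplit(cod, "")[[1]]
    rows <- list()
    for (pos in 1:3) {
      for (b in setdiff(nt, chars[pos])) {
        to <- chars
        to[pos] <- b
        to <- paste(to, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          to = to, pos = pos,
          ts = .isTransition(chars[pos], b),
          stop = to %in% .STOP_CODONS,
          syn = identical(unname(tab$aa[to]), unname(tab$aa[cod])),
          stringsAsFactors = FALSE
        )
      }
    }
    out[[cod]] <- do.call(rbind, rows)
  }
  out
})

.translateCodons <- function(codons) {
  unname(.codonTable$aa[codons])
}

# Per-codon substitution kernel under a K80-style nucleotide model with an
# omega multiplier on nonsynonymous changes; changes into stop codons are
# forbidden. Rates are normalised so that one unit of branch length gives an
# expected one substitution per codon under omega = 1 at uniform sense-codon
# frequencies.
.codonRates <- function(kappa) {
  nb <- .codonNeighbours
  syn <- numeric(length(nb))
  nonsyn <- numeric(length(nb))
  names(syn) <- names(nonsyn) <- names(nb)
  for (cod in names(nb)) {
    x <- nb[[cod]]
    x <- x[!x$stop, , drop = FALSE]
    w <- ifelse(x$ts, kappa, 1)
    syn[cod] <- sum(w[x$syn])
    nonsyn[cod] <- sum(w[!x$syn])
  }
  nu <- mean(syn + nonsyn)  # neutral normaliser
  list(syn = syn / nu, nonsyn = nonsyn / nu, nu = nu, kappa = kappa)
}

# Nei-Gojobori-style synonymous/nonsynonymous site counts per codon, with
# optional transition/transversion weighting of mutational opportunity.
# Changes into stop codons are excluded from the opportunity set.
.siteCounts <- function(kappa = 1) {
  nb <- .codonNeighbours
  S <- numeric(length(nb))
  names(S) <- names(nb)
  for (cod in names(nb)) {
    x <- nb[[cod]]
    x <- x[!x$stop, , drop = FALSE]
    w <- ifelse(x$ts, kappa, 1)
    S[cod] <- 3 * sum(w[x$syn]) / sum(w)
  }
  list(S = S, N = 3 - S)
}

# Classify each differing nucleotide position between two sense codons as a
# synonymous or nonsynonymous single-site change in the context of `from`.
# Returns c(sd, nd) integer counts.
.codonDiffCounts <- function(from, to) {
  if (from == to) return(c(sd = 0L, nd = 0L))
  f <- strsplit(from, "")[[1]]
  t <- strsplit(to, "")[[1]]
  sd <- 0L; nd <- 0L
  for (pos in which(f != t)) {
    one <- f
    one[pos] <- t[pos]
    one <- paste(one, collapse = "")
    if (!one %in% .STOP_CODONS &&
        identical(unname(.codonTable$aa[one]), unname(.codonTable$aa[from]))) {
      sd <- sd + 1L
    } else {
      nd <- nd + 1L
    }
  }
  c(sd = sd, nd = nd)
}

.randomSenseCodons <- function(n) {
  sample(.codonTable$sense, n, replace = TRUE)
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
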