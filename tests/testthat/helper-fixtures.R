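# Shared fixtures and independent oracles built in code.

# peptides of all transcripts of one species in an emitTranscripts result
emittedPeptides <- function(emitted, species) {
  ss <- emitted$fasta[[species]]
  vapply(names(ss), function(id) translateCds(as.character(ss[[id]])),
         character(1))
}

# --- independent Gotoh affine-gap global aligner (score only) -------------
# Same cost convention as the implementation's documented one: a gap of
# length L costs open + L * extend. Plain 3-state dynamic programme.
oracleGlobalScore <- function(a, b, mat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in B (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in A
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) {
    X[i, 1] <- -open - ext * (i - 1)
  }
  for (j in seq_len(m) + 1) {
    Y[1, j] <- -open - ext * (j - 1)
  }
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

randomPeptide <- function(len) {
  paste(sample(rownames(blosum62)[1:20], len, replace = TRUE),
        collapse = "")
}

# --- naive six-frame ORF scanner (oracle for extractOrfs) -----------------
oracleOrfLengths <- function(seq, minLen, maxLen) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  gc <- Biostrings::GENETIC_CODE
  out <- integer(0)
  for (s in c(seq, revcomp(seq))) {
    for (f in 0:2) {
      ncod <- (nchar(s) - f) %/% 3
      if (ncod < 1) next
      cods <- substring(s, f + 3 * seq_len(ncod) - 2, f + 3 * seq_len(ncod))
      aa <- ifelse(cods %in% names(gc), gc[cods], "X")
      # every maximal ATG..stop run
      i <- 1
      while (i <= ncod) {
        if (aa[i] == "M") {
          j <- i
          while (j <= ncod && aa[j] != "*") j <- j + 1
          if (j <= ncod) {        # stop found
            len <- j - i
            if (len >= minLen && len <= maxLen &&
                !any(aa[i:(j - 1)] == "X"))
              out <- c(out, len)
            i <- j + 1            # longest-per-segment: jump past stop
          } else break
        } else i <- i + 1
      }
    }
  }
  out
}

# --- naive species-overlap reconciliation (oracle) ------------------------
# Independent route: phangorn tree utilities, per-subtree re-checks.
oracleDelimit <- function(tree, speciesOf) {
  ntip <- length(tree$tip.label)
  allNodes <- ntip + seq_len(tree$Nnode)
  tipsUnder <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    tree$tip.label[unlist(phangorn::Descendants(tree, v, "tips"))]
  }
  spUnder <- function(v) unique(unname(speciesOf[tipsUnder(v)]))
  isBad <- function(v) {  # non-local duplication node
    if (v <= ntip) return(FALSE)
    ch <- phangorn::Children(tree, v)
    if (length(ch) != 2) return(FALSE)
    overlap <- length(intersect(spUnder(ch[1]), spUnder(ch[2]))) > 0
    overlap && length(spUnder(v)) > 1
  }
  cleanSubtree <- function(v) {
    if (v <= ntip) return(TRUE)
    inner <- c(v, unlist(phangorn::Descendants(tree, v, "all")))
    inner <- inner[inner > ntip]
    !any(vapply(inner, isBad, logical(1)))
  }
  parent <- function(v) tree$edge[tree$edge[, 2] == v, 1]
  roots <- c(allNodes, seq_len(ntip))
  roots <- roots[vapply(roots, function(v) {
    if (!cleanSubtree(v)) return(FALSE)
    p <- parent(v)
    length(p) == 0 || !cleanSubtree(p)
  }, logical(1))]
  lapply(roots, function(v) sort(tipsUnder(v)))
}

# canonical form of a partition (set of leaf sets)
canonicalPartition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, paste, character(1), collapse = "|"))]
}

# enumerate all rooted binary leaf-labelled topologies over labels
enumerateRootedTrees <- function(labels) {
  if (length(labels) == 1) return(labels)
  out <- character(0)
  n <- length(labels)
  # split: first label goes left; choose remaining members of left set
  rest <- labels[-1]
  for (k in 0:(n - 2)) {
    combs <- if (k == 0) list(integer(0))
    else utils::combn(seq_along(rest), k, simplify = FALSE)
    for (cc in combs) {
      left <- c(labels[1], rest[cc])
      right <- setdiff(labels, left)
      for (l in enumerateRootedTrees(left))
        for (r in enumerateRootedTrees(right))
          out <- c(out, paste0("(", l, ",", r, ")"))
    }
  }
  out
}

randomRootedTree <- function(labels) {
  ape::rtree(length(labels), tip.label = labels, rooted = TRUE)
}

# branch-test rows realising prescribed per-clade counts: tested branches,
# significant terminal/internal branches, tested orthogroups and the number
# of orthogroups holding the significant branches
syntheticTests <- function(spec) {
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    ogNames <- paste0(gsub("/", "", s$clade), "_og",
                      seq_len(s$ogTested))
    sigSlots <- s$termSig + s$intSig
    nb <- s$tested
    ogOf <- rep(ogNames, length.out = nb)
    kind <- rep("terminal", nb)
    sig <- rep(FALSE, nb)
    if (sigSlots > 0) {
      sig[seq_len(sigSlots)] <- TRUE
      kind[seq_len(sigSlots)] <-
        c(rep("terminal", s$termSig), rep("internal", s$intSig))
      ogOf[seq_len(sigSlots)] <- rep(ogNames[seq_len(s$ogSig)],
                                     length.out = sigSlots)
    }
    rows[[i]] <- data.frame(
      orthogroup = ogOf,
      branch = paste0(gsub("/", "", s$clade), "_b", seq_len(nb)),
      branch_kind = kind, p_raw = ifelse(sig, 1e-6, 0.9),
      p_adj = ifelse(sig, 1e-5, 0.95), significant = sig,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# the published per-clade branch-selection counts for the V1R repertoire
printedSelectionCounts <- function() {
  data.frame(
    clade = c("A/B", "C", "D", "E", "F", "G", "H", "I", "J/K", "L", "N"),
    termSig = c(3L, 3L, 5L, 0L, 2L, 6L, 3L, 2L, 0L, 0L, 0L),
    intSig = c(2L, 2L, 0L, 1L, 0L, 2L, 0L, 0L, 1L, 0L, 0L),
    tested = c(119L, 235L, 119L, 122L, 45L, 101L, 125L, 100L, 57L, 7L,
               5L),
    ogTested = c(11L, 35L, 13L, 16L, 5L, 13L, 15L, 13L, 4L, 1L, 1L),
    ogSig = c(3L, 4L, 4L, 1L, 1L, 5L, 3L, 2L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
}
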