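# round half away from zero, matching hand-rounding of printed percentages
.roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Select orthogroups eligible for selection testing
#'
#' Only orthogroups with at least \code{minMembers} member sequences
#' (orthologs and paralogs counted together) are tested.
#'
#' @param ogs an \code{\linkS4class{OrthogroupSet}}
#' @param minMembers minimum member count (default 4)
#' @return the subsetted \code{OrthogroupSet}
#' @export
eligibleOrthogroups <- function(ogs, minMembers = 4L) {
  keep <- lengths(ogs@members) >= minMembers
  new("OrthogroupSet", table = ogs@table[keep, , drop = FALSE],
      members = ogs@members[keep])
}

#' Counting-based branch dN/dS screen
#'
#' A deliberately simple screen used where externally computed
#' branch-site likelihood results are not available; its outputs carry
#' \code{source = "internal_screen"} so they are never mistaken for them.
#' Ancestral codons are reconstructed by Fitch parsimony per codon column
#' (ties resolved toward the lexicographically smallest codon). Per branch,
#' synonymous and nonsynonymous sites (S, N) are counted on the parent
#' sequence in the Nei-Gojobori style and each differing nucleotide
#' position is classified as a synonymous or nonsynonymous single-site
#' change, giving integer counts Sd and Nd. The one-sided p-value is the
#' binomial tail probability of at least Nd nonsynonymous changes among
#' Nd + Sd given the neutral expectation N/(N+S). Branches with no changes
#' are untested and omitted.
#'
#' @param codonAln named character vector or \code{DNAStringSet} of
#'   equal-length in-frame codon rows (gapped columns are dropped codon-wise)
#' @param tree rooted \code{phylo} whose tip labels match the alignment
#'   names
#' @param orthogroup orthogroup name recorded in the output
#' @param kappa transition/transversion weighting of the site counts
#'   (1 = classic equal-rate counting)
#' @return data.frame of \code{BranchTest} rows: orthogroup, branch,
#'   branch_kind, dN, dS, n_syn_sites, n_nonsyn_sites, sd, nd, p_raw,
#'   source
#' @export
branchDndsScreen <- function(codonAln, tree, orthogroup = "OG", kappa = 1) {
  if (inherits(codonAln, "DNAStringSet")) {
    nm <- names(codonAln)
    codonAln <- as.character(codonAln)
    names(codonAln) <- nm
  }
  if (length(unique(nchar(codonAln))) != 1L)
    stop("codon alignment rows must have equal length")
  if (nchar(codonAln[[1]]) %% 3 != 0)
    stop("alignment width must be a codon multiple")
  if (!all(tree$tip.label %in% names(codonAln)))
    stop("tree tips missing from the alignment")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  codons <- lapply(codonAln[tree$tip.label], .splitCodons)
  ncol <- length(codons[[1]])
  ok <- vapply(seq_len(ncol), function(j) {
    col <- vapply(codons, `[[`, character(1), j)
    all(col %in% .codonTable$sense)
  }, logical(1))
  if (any(vapply(seq_len(ncol), function(j) {
    col <- vapply(codons, `[[`, character(1), j)
    any(col %in% .STOP_CODONS)
  }, logical(1))))
    stop("stop codon in codon alignment")
  cols <- which(ok)
  if (!length(cols)) stop("no gap-free codon columns to analyse")

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  anc <- matrix(NA_character_, ntip + nnode, length(cols))
  for (k in seq_along(cols)) {
    j <- cols[k]
    col <- vapply(codons, `[[`, character(1), j)
    anc[, k] <- .fitchColumn(tree, col)
  }

  sites <- .siteCounts(kappa)
  rows <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    pseq <- anc[par, ]
    cseq <- anc[chi, ]
    S <- sum(sites$S[pseq])
    N <- sum(sites$N[pseq])
    sd <- 0L; nd <- 0L
    for (k in which(pseq != cseq)) {
      d <- .codonDiffCounts(pseq[k], cseq[k])
      sd <- sd + d[["sd"]]
      nd <- nd + d[["nd"]]
    }
    if (sd + nd == 0L) next  # untested branch
    pNeutral <- N / (N + S)
    p <- stats::pbinom(nd - 1L, nd + sd, pNeutral, lower.tail = FALSE)
    dN <- nd / N
    dS <- sd / S
    rows[[length(rows) + 1L]] <- data.frame(
      orthogroup = orthogroup,
      branch = if (chi <= ntip) tree$tip.label[chi]
               else paste0("node", chi),
      branch_kind = if (chi <= ntip) "terminal" else "internal",
      dN = dN, dS = dS, n_syn_sites = S, n_nonsyn_sites = N,
      sd = sd, nd = nd, p_raw = p, source = "internal_screen",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(orthogroup = character(), branch = character(),
                      branch_kind = character(), dN = numeric(),
                      dS = numeric(), n_syn_sites = numeric(),
                      n_nonsyn_sites = numeric(), sd = integer(),
                      nd = integer(), p_raw = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Fitch parsimony for one codon column; returns states for all nodes
# (tips then internals). Ties at the root and at top-down assignment are
# broken toward the lexicographically smallest codon.
.fitchColumn <- function(tree, tipStates) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tipStates[i]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (v in .postorderNodes(tree)) {
    if (v <= ntip) next
    ch <- kids[[as.character(v)]]
    s <- sets[[ch[1]]]
    for (c2 in ch[-1]) {
      inter <- intersect(s, sets[[c2]])
      s <- if (length(inter)) inter else union(s, sets[[c2]])
    }
    sets[[v]] <- s
  }
  states <- character(ntip + tree$Nnode)
  root <- ntip + 1L
  states[root] <- sort(sets[[root]])[1]
  for (e in .preorderEdges(tree)) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    if (chi <= ntip) {
      states[chi] <- tipStates[chi]
    } else {
      states[chi] <- if (states[par] %in% sets[[chi]]) states[par]
      else sort(sets[[chi]])[1]
    }
  }
  states
}

#' Ingest externally computed per-branch selection tests
#'
#' Reads a tab-delimited table (orthogroup, branch, branch_kind, p_raw)
#' such as exported branch-site likelihood results. Rows with p outside
#' [0, 1] are rejected with a message; the rest are kept with
#' \code{source = "external"}. Adjusted p-values are left unset until
#' \code{\link{fdrCorrect}}.
#'
#' @param x path to a TSV with a header, or an equivalent data.frame
#' @return data.frame of BranchTest rows
#' @export
ingestExternalTests <- function(x) {
  tab <- if (is.character(x)) readTsv(x) else x
  need <- c("orthogroup", "branch", "branch_kind", "p_raw")
  if (!all(need %in% names(tab)))
    stop("external test table needs columns: ",
         paste(need, collapse = ", "))
  tab$p_raw <- as.numeric(tab$p_raw)
  bad <- is.na(tab$p_raw) | tab$p_raw < 0 | tab$p_raw > 1
  if (any(bad))
    message("ingestExternalTests: rejected ", sum(bad),
            " row(s) with p outside [0, 1]")
  tab <- tab[!bad, , drop = FALSE]
  tab$source <- rep("external", nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Benjamini-Hochberg correction of branch tests
#'
#' Step-up FDR correction at level \code{q}, either pooled over all tested
#' branches (default) or within each orthogroup. A branch is significant
#' iff its adjusted p is at or below \code{q}.
#'
#' @param tests data.frame with \code{p_raw} (and \code{orthogroup} when
#'   \code{scope = "per_orthogroup"})
#' @param q FDR level (default 0.05)
#' @param scope \code{"pooled"} or \code{"per_orthogroup"}
#' @return the input with \code{p_adj} and \code{significant} columns
#' @export
fdrCorrect <- function(tests, q = 0.05,
                       scope = c("pooled", "per_orthogroup")) {
  scope <- match.arg(scope)
  if (!nrow(tests)) {
    tests$p_adj <- numeric(0)
    tests$significant <- logical(0)
    return(tests)
  }
  if (scope == "pooled") {
    tests$p_adj <- stats::p.adjust(tests$p_raw, method = "BH")
  } else {
    tests$p_adj <- NA_real_
    for (og in unique(tests$orthogroup)) {
      idx <- tests$orthogroup == og
      tests$p_adj[idx] <- stats::p.adjust(tests$p_raw[idx], method = "BH")
    }
  }
  tests$significant <- tests$p_adj <= q
  tests
}

#' Aggregate branch tests into a per-clade selection summary
#'
#' One row per clade plus a Total row, in the shape of a branch-selection
#' summary table: counts of significant terminal and internal branches,
#' tested branches and orthogroups, the percentage of tested branches
#' significant, the percentage of tested orthogroups with at least one
#' significant branch, and the ids of those orthogroups. Percentages are
#' rounded half-up to two decimals; a clade with zero tested branches
#' reports 0.00.
#'
#' @param tests FDR-corrected data.frame from \code{\link{fdrCorrect}}
#' @param cladeMap named character vector: orthogroup name -> clade
#' @param cladeOrder optional display order of clades
#' @return data.frame with columns clade, terminal_sig, internal_sig,
#'   total_sig, tested_branches, pct_branches, tested_orthogroups,
#'   pct_orthogroups, orthogroup_ids
#' @export
summarizeSelection <- function(tests, cladeMap, cladeOrder = NULL) {
  tests$clade <- unname(cladeMap[tests$orthogroup])
  tests$clade[is.na(tests$clade)] <- "unplaced"
  clades <- if (!is.null(cladeOrder)) cladeOrder
  else sort(unique(tests$clade))
  rowFor <- function(sub, label) {
    sig <- sub[sub$significant, , drop = FALSE]
    ogTested <- unique(sub$orthogroup)
    ogSig <- sort(unique(sig$orthogroup))
    nT <- nrow(sub)
    data.frame(
      clade = label,
      terminal_sig = sum(sig$branch_kind == "terminal"),
      internal_sig = sum(sig$branch_kind == "internal"),
      total_sig = nrow(sig),
      tested_branches = nT,
      pct_branches = if (nT) .roundHalfUp(100 * nrow(sig) / nT, 2) else 0,
      tested_orthogroups = length(ogTested),
      pct_orthogroups = if (length(ogTested))
        .roundHalfUp(100 * length(ogSig) / length(ogTested), 2) else 0,
      orthogroup_ids = if (length(ogSig))
        paste(ogSig, collapse = ", ") else "-",
      stringsAsFactors = FALSE)
  }
  rows <- lapply(clades, function(cl)
    rowFor(tests[tests$clade == cl, , drop = FALSE], cl))
  out <- do.call(rbind, rows)
  out <- rbind(out, rowFor(tests, "Total"))
  out$orthogroup_ids[out$clade == "Total"] <- "NA"
  rownames(out) <- NULL
  out
}

#' Headline terminal/internal significance fractions
#'
#' The two repertoire-level fractions quoted alongside the per-clade
#' table: significant terminal branches over tested terminal branches
#' (genes) and significant internal branches over tested internal
#' branches (deeper branches), as percentages rounded half-up to one
#' decimal.
#'
#' @param nTerminalSig,nInternalSig significant branch counts
#' @param nTestedGenes tested terminal branches (genes)
#' @param nTestedBranches all tested branches
#' @return named numeric vector (pct_genes, pct_internal)
#' @export
headlineFractions <- function(nTerminalSig, nInternalSig, nTestedGenes,
                              nTestedBranches) {
  c(pct_genes = .roundHalfUp(100 * nTerminalSig / nTestedGenes, 1),
    pct_internal = .roundHalfUp(
      100 * nInternalSig / (nTestedBranches - nTestedGenes), 1))
}
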