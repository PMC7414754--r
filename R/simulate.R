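#' Default six-species Mus phylogeny
#'
#' Rooted topology
#' \code{((((domesticus,(spicilegus,macedonicus)),spretus),caroli),pahari)}
#' with branch lengths scaled so that the root-to-tip path is about 0.07
#' expected substitutions per codon site, i.e. genus-level divergence at
#' desk scale. Rat is available only as an outgroup label for rooting
#' supplied trees, never as a simulated lineage.
#'
#' @param rootToTip target root-to-tip path length (substitutions per codon)
#' @return a rooted \code{phylo} with 6 tips
#' @examples
#' tr <- musSpeciesTree()
#' ape::is.rooted(tr)
#' @export
musSpeciesTree <- function(rootToTip = 0.07) {
  nwk <- paste0(
    "((((domesticus:4,(spicilegus:2,macedonicus:2):2):2,spretus:6):2,",
    "caroli:8):2,pahari:10);")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- tr$edge.length * (rootToTip / 10)
  tr
}

.checkSpeciesTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("species tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("species names must be unique")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("species tree needs nonnegative branch lengths")
  invisible(tree)
}

# Name of the species-tree branch leading into node `v` (tip label for tips,
# node number as character otherwise).
.branchName <- function(tree, v) {
  if (v <= length(tree$tip.label)) tree$tip.label[v] else as.character(v)
}

#' Simulate a receptor family along a species tree
#'
#' Runs an exact per-branch Gillespie simulation of the linear
#' birth-and-death process: each gene lineage on a branch duplicates at rate
#' \code{dupRate} and dies at rate \code{lossRate} (per unit branch length);
#' a death is recorded as a pseudogenization with probability
#' \code{pseudoProb}, otherwise as a deletion. Lineages surviving to a tip
#' become gene copies of that species. Pseudogenized lineages are recorded
#' in the event table but never produce copies, mirroring
#' transcriptome-based detection.
#'
#' True orthogroup labels follow the lineage founders: every root gene
#' founds one orthogroup, and a duplication on an internal species branch
#' founds a new orthogroup for the derived copy (such duplications separate
#' groups that span several species); duplications on terminal branches
#' stay within their parent orthogroup as within-species paralogs.
#'
#' @param speciesTree rooted \code{phylo} with named tips
#' @param params a \code{\linkS4class{SimParams}}; the run is deterministic
#'   given \code{params@seed}
#' @return a \code{\linkS4class{TruthRecord}}
#' @examples
#' tr <- simulateFamily(musSpeciesTree(),
#'                      SimParams(seed = 1L, nRootGenes = 3L,
#'                                dupRate = 0, lossRate = 0))
#' length(trueOrthogroups(tr))
#' @export
simulateFamily <- function(speciesTree, params) {
  .checkSpeciesTree(speciesTree)
  validObject(params)
  set.seed(params@seed)
  lam <- params@dupRate
  mu <- params@lossRate
  ntip <- length(speciesTree$tip.label)
  rootNode <- ntip + 1L

  childrenOf <- function(v) speciesTree$edge[speciesTree$edge[, 1] == v, 2]
  edgeLen <- function(v)
    speciesTree$edge.length[speciesTree$edge[, 2] == v]

  env <- new.env()
  env$copy <- 0L
  env$founder <- 0L
  env$node <- 0L
  env$events <- list()
  env$og <- character()
  env$sp <- character()
  env$nodeBranch <- character()

  newFounder <- function() {
    env$founder <- env$founder + 1L
    paste0("OG", env$founder)
  }

  # One lineage entering the branch that leads into species-tree node `v`,
  # with `rem` branch length still to travel. Returns NULL (lineage dead) or
  # list(str = newick fragment sans top length, len = top edge length).
  onBranch <- function(v, rem, founder) {
    rate <- lam + mu
    w <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (w >= rem) {
      res <- atNode(v, founder)
      if (is.null(res)) return(NULL)
      res$len <- res$len + rem
      return(res)
    }
    if (stats::runif(1) < lam / rate) {  # duplication
      env$events[[length(env$events) + 1L]] <-
        list(branch = .branchName(speciesTree, v), kind = "duplication")
      terminal <- v <= ntip
      fL <- founder
      fR <- if (terminal) founder else newFounder()
      a <- onBranch(v, rem - w, fL)
      b <- onBranch(v, rem - w, fR)
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a)) { b$len <- b$len + w; return(b) }
      if (is.null(b)) { a$len <- a$len + w; return(a) }
      env$node <- env$node + 1L
      lab <- paste0("d", env$node)
      env$nodeBranch[lab] <- .branchName(speciesTree, v)
      list(str = paste0("(", a$str, ":", a$len, ",", b$str, ":", b$len,
                        ")", lab),
           len = w)
    } else {  # loss
      kind <- if (stats::runif(1) < params@pseudoProb)
        "pseudogenization" else "loss"
      env$events[[length(env$events) + 1L]] <-
        list(branch = .branchName(speciesTree, v), kind = kind)
      NULL
    }
  }

  # Lineage arriving at species-tree node `v`.
  atNode <- function(v, founder) {
    if (v <= ntip) {
      env$copy <- env$copy + 1L
      g <- paste0("g", env$copy)
      lab <- paste0(speciesTree$tip.label[v], "|", g, "|t1")
      env$og[g] <- founder
      env$sp[g] <- speciesTree$tip.label[v]
      env$nodeBranch[lab] <- speciesTree$tip.label[v]
      return(list(str = lab, len = 0))
    }
    kids <- childrenOf(v)
    subs <- list()
    for (k in kids) {
      r <- onBranch(k, edgeLen(k), founder)
      if (!is.null(r)) subs[[length(subs) + 1L]] <- r
    }
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L) return(subs[[1]])
    env$node <- env$node + 1L
    lab <- paste0("s", env$node)
    env$nodeBranch[lab] <- as.character(v)
    inner <- paste(vapply(subs, function(r) paste0(r$str, ":", r$len),
                          character(1)), collapse = ",")
    list(str = paste0("(", inner, ")", lab), len = 0)
  }

  fams <- list()
  for (i in seq_len(params@nRootGenes)) {
    founder <- newFounder()
    r <- atNode(rootNode, founder)
    if (!is.null(r)) fams[[length(fams) + 1L]] <- r
  }

  # Join surviving families on a ladder of ancient duplications so that the
  # full gene tree is binary and families sit rootGeneDivergence/2 from the
  # join below them.
  half <- params@rootGeneDivergence / 2
  tree <- NULL
  if (length(fams) >= 1L) {
    acc <- paste0(fams[[1]]$str, ":", fams[[1]]$len + half)
    if (length(fams) >= 2L) {
      for (i in 2:length(fams)) {
        env$node <- env$node + 1L
        lab <- paste0("r", env$node)
        env$nodeBranch[lab] <- as.character(rootNode)
        acc <- paste0("(", acc, ",", fams[[i]]$str, ":",
                      fams[[i]]$len + half, ")", lab,
                      if (i < length(fams)) paste0(":", half) else "")
      }
    }
    nwk <- paste0(acc, ";")
    ncopies <- env$copy
    tree <- if (ncopies >= 2L) ape::read.tree(text = nwk) else NULL
  }

  events <- if (length(env$events))
    data.frame(branch = vapply(env$events, `[[`, character(1), "branch"),
               kind = vapply(env$events, `[[`, character(1), "kind"),
               stringsAsFactors = FALSE)
  else data.frame(branch = character(), kind = character(),
                  stringsAsFactors = FALSE)

  new("TruthRecord", geneTree = tree, speciesTree = speciesTree,
      orthogroups = env$og, copySpecies = env$sp, events = events,
      variantLabels = character(), nodeBranch = env$nodeBranch,
      params = params)
}

# omega multiplier for the gene-tree edge ending at node with label `lab`,
# looked up through the species branch recorded for that node.
.edgeOmega <- function(truth, lab) {
  params <- truth@params
  br <- truth@nodeBranch[lab]
  cls <- "default"
  if (!is.na(br) && br %in% names(params@branchClasses))
    cls <- params@branchClasses[[br]]
  if (!cls %in% names(params@omegaMap)) cls <- "default"
  unname(params@omegaMap[[cls]])
}

#' Evolve codon sequences along a simulated gene tree
#'
#' Starting from a random stop-free root sequence with a frozen ATG
#' initiator, sequences evolve down every gene-tree edge under a
#' continuous-time codon process: a K80-style nucleotide kernel with
#' transition/transversion ratio \code{kappa}, nonsynonymous changes at
#' \code{omega} times the synonymous rate, stop codons forbidden, uniform
#' codon frequencies. Branch lengths are expected substitutions per codon
#' site under the neutral (omega = 1) scaling. The per-edge omega is taken
#' from \code{omegaMap} via the branch class of the species-tree branch the
#' edge runs along.
#'
#' @param truth a \code{\linkS4class{TruthRecord}} from
#'   \code{\link{simulateFamily}}
#' @param params the same \code{SimParams}; \code{rootSequence} may override
#'   the random root
#' @param rootSequence optional explicit root DNA sequence (codon multiple,
#'   no internal stop)
#' @return named character vector of codon sequences for every gene-tree
#'   node (tips and internal nodes); deterministic given the seed
#' @export
evolveSequences <- function(truth, params = truth@params,
                            rootSequence = NULL) {
  tree <- truth@geneTree
  if (is.null(tree)) {
    # 0 or 1 surviving copy: still emit a sequence per copy from the root
    set.seed(params@seed + 1L)
    root <- .makeRootSeq(params, rootSequence)
    out <- character()
    for (g in names(truth@orthogroups)) {
      lab <- paste0(truth@copySpecies[[g]], "|", g, "|t1")
      out[lab] <- paste(root, collapse = "")
    }
    return(out)
  }
  set.seed(params@seed + 1L)
  root <- .makeRootSeq(params, rootSequence)
  rates <- .codonRates(params@kappa)
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else as.character(ntip + seq_len(tree$Nnode)))
  seqs <- vector("list", ntip + tree$Nnode)
  rootIdx <- ntip + 1L
  seqs[[rootIdx]] <- root
  ord <- .preorderEdges(tree)
  for (e in ord) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    lab <- labels[chi]
    omega <- .edgeOmega(truth, lab)
    seqs[[chi]] <- .evolveBranch(seqs[[par]], tree$edge.length[e],
                                 omega, rates)
  }
  out <- vapply(seqs, function(s) paste(s, collapse = ""), character(1))
  names(out) <- labels
  out
}

.makeRootSeq <- function(params, rootSequence) {
  if (!is.null(rootSequence)) {
    if (nchar(rootSequence) %% 3 != 0)
      stop("root sequence length must be a codon multiple")
    cods <- .splitCodons(rootSequence)
    if (any(cods %in% .STOP_CODONS))
      stop("root sequence must not contain stop codons")
    return(cods)
  }
  c("ATG", .randomSenseCodons(params@geneLength - 1L))
}

# Gillespie simulation of the codon process on one branch. Codon 1 (the
# initiator) is frozen.
.evolveBranch <- function(codons, len, omega, rates) {
  if (len <= 0) return(codons)
  L <- length(codons)
  if (L < 2L) return(codons)
  r <- rates$syn[codons] + omega * rates$nonsyn[codons]
  r[1L] <- 0
  t <- 0
  repeat {
    tot <- sum(r)
    if (tot <= 0) break
    t <- t + stats::rexp(1, tot)
    if (t > len) break
    i <- sample.int(L, 1L, prob = r)
    nb <- .codonNeighbours[[codons[i]]]
    nb <- nb[!nb$stop, , drop = FALSE]
    # target weight = kappa^[transition] * omega^[nonsynonymous]
    w <- ifelse(nb$ts, rates$kappa, 1) * ifelse(nb$syn, 1, omega)
    j <- sample.int(nrow(nb), 1L, prob = w)
    codons[i] <- nb$to[j]
    r[i] <- rates$syn[codons[i]] + omega * rates$nonsyn[codons[i]]
  }
  codons
}

.preorderEdges <- function(tree) {
  # parent-before-child edge order
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ord <- integer(0)
  stack <- which(tree$edge[, 1] == root)
  while (length(stack)) {
    e <- stack[1]
    stack <- stack[-1]
    ord <- c(ord, e)
    chi <- tree$edge[e, 2]
    stack <- c(which(tree$edge[, 1] == chi), stack)
  }
  ord
}
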