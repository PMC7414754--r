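#' @import methods
NULL

setOldClass("phylo")

#' Simulation parameters for the receptor-family simulator
#'
#' Holds every tunable of the codon-level birth-and-death simulator:
#' duplication/loss rates per gene per unit branch length, the probability
#' that a loss is recorded as a pseudogenization, the per-branch-class
#' dN/dS multipliers, the transition/transversion ratio, gene length in
#' codons, and the transcript-variant emission model.
#'
#' @slot nRootGenes number of ancestral genes at the root of the species tree
#' @slot dupRate duplication rate (events per gene per unit branch length)
#' @slot lossRate loss rate (events per gene per unit branch length)
#' @slot pseudoProb probability a loss is recorded as a pseudogenization
#'   rather than a clean deletion
#' @slot omegaMap named numeric vector of dN/dS multipliers, one per branch
#'   class; must contain a \code{"default"} entry
#' @slot branchClasses named character vector mapping species-tree branches
#'   (named by the tip label or internal node number of the branch's child)
#'   to omega classes; unnamed branches take \code{"default"}
#' @slot kappa transition/transversion rate ratio of the nucleotide kernel
#' @slot geneLength gene length in codons (initiator codon included)
#' @slot pVariant probability that a surviving gene emits one extra
#'   transcript (a transcript variant) in addition to its primary transcript
#' @slot variantWeights sampling weights over the three variant classes
#'   \code{same_peptide}, \code{truncated}, \code{end_modified}; must sum to 1
#' @slot truncFrac fraction of codons removed from the 3' end of a
#'   \code{truncated} variant
#' @slot endModCodons number of C-terminal codons resampled in an
#'   \code{end_modified} variant
#' @slot synVariantChanges number of synonymous substitutions applied to a
#'   \code{same_peptide} variant so that it differs at the DNA level
#' @slot rootGeneDivergence branch length separating ancestral root genes in
#'   the joined gene tree (substitutions per codon site)
#' @slot seed integer seed; every stochastic operation derives its stream
#'   from it, and simulation refuses to run without one
#' @export
setClass("SimParams", representation(
  nRootGenes = "integer",
  dupRate = "numeric",
  lossRate = "numeric",
  pseudoProb = "numeric",
  omegaMap = "numeric",
  branchClasses = "character",
  kappa = "numeric",
  geneLength = "integer",
  pVariant = "numeric",
  variantWeights = "numeric",
  truncFrac = "numeric",
  endModCodons = "integer",
  synVariantChanges = "integer",
  rootGeneDivergence = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nRootGenes < 1L) msg <- c(msg, "nRootGenes must be >= 1")
  if (object@dupRate < 0 || object@lossRate < 0)
    msg <- c(msg, "duplication and loss rates must be nonnegative")
  for (p in c(object@pseudoProb, object@pVariant, object@truncFrac))
    if (p < 0 || p > 1) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!"default" %in% names(object@omegaMap))
    msg <- c(msg, "omegaMap must contain a 'default' class")
  if (any(object@omegaMap < 0)) msg <- c(msg, "omega multipliers must be >= 0")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be positive")
  if (object@geneLength < 100L)
    msg <- c(msg, "geneLength must be at least 100 codons")
  if (!isTRUE(all.equal(sum(object@variantWeights), 1)) ||
      !setequal(names(object@variantWeights),
                c("same_peptide", "truncated", "end_modified")))
    msg <- c(msg, paste("variantWeights must be named same_peptide/truncated/",
                        "end_modified and sum to 1"))
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "an explicit integer seed is required")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param nRootGenes,dupRate,lossRate,pseudoProb,omegaMap,branchClasses,kappa
#'   see the slots of \code{\linkS4class{SimParams}}
#' @param geneLength,pVariant,variantWeights,truncFrac,endModCodons see slots
#' @param synVariantChanges,rootGeneDivergence,seed see slots
#' @return a validated \code{SimParams} object
#' @examples
#' SimParams(seed = 1L, nRootGenes = 5L, dupRate = 0, lossRate = 0)
#' @export
SimParams <- function(seed,
                      nRootGenes = 10L,
                      dupRate = 0.5,
                      lossRate = 0.4,
                      pseudoProb = 0.5,
                      omegaMap = c(default = 0.5),
                      branchClasses = character(),
                      kappa = 2,
                      geneLength = 300L,
                      pVariant = 0.25,
                      variantWeights = c(same_peptide = 0.6,
                                         truncated = 0.25,
                                         end_modified = 0.15),
                      truncFrac = 0.4,
                      endModCodons = 6L,
                      synVariantChanges = 3L,
                      rootGeneDivergence = 0.3) {
  if (missing(seed) || is.null(seed))
    stop("SimParams: an explicit seed is required; there is no wall-clock ",
         "fallback")
  new("SimParams",
      nRootGenes = as.integer(nRootGenes), dupRate = dupRate,
      lossRate = lossRate, pseudoProb = pseudoProb, omegaMap = omegaMap,
      branchClasses = branchClasses, kappa = kappa,
      geneLength = as.integer(geneLength), pVariant = pVariant,
      variantWeights = variantWeights, truncFrac = truncFrac,
      endModCodons = as.integer(endModCodons),
      synVariantChanges = as.integer(synVariantChanges),
      rootGeneDivergence = rootGeneDivergence, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nRootGenes, "root genes,",
      "dup", object@dupRate, "/ loss", object@lossRate,
      "per gene per unit length;",
      object@geneLength, "codons; kappa", object@kappa,
      "; seed", object@seed, "\n")
  cat("  omega:", paste(names(object@omegaMap), object@omegaMap,
                        sep = "=", collapse = ", "), "\n")
})

#' Receptor gene model used for open-reading-frame extraction
#'
#' V1Rs are mostly single-exon receptors of roughly 300 codons; the default
#' bounds of 270-400 codons with a required initiator and terminator bracket
#' that architecture while remaining configurable.
#'
#' @slot minLen minimum ORF length in codons (stop codon excluded)
#' @slot maxLen maximum ORF length in codons
#' @slot requireStart require an ATG initiator
#' @slot requireStop require a terminator immediately after the ORF
#' @export
setClass("GeneModel", representation(
  minLen = "integer", maxLen = "integer",
  requireStart = "logical", requireStop = "logical"
))

setValidity("GeneModel", function(object) {
  if (object@minLen < 1L || object@minLen > object@maxLen)
    "need 0 < minLen <= maxLen" else TRUE
})

#' @param minLen,maxLen,requireStart,requireStop see
#'   \code{\linkS4class{GeneModel}} slots
#' @return a validated \code{GeneModel}
#' @rdname GeneModel-class
#' @export
GeneModel <- function(minLen = 270L, maxLen = 400L,
                      requireStart = TRUE, requireStop = TRUE) {
  new("GeneModel", minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      requireStart = requireStart, requireStop = requireStop)
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel: [", object@minLen, ",", object@maxLen, "] codons;",
      if (object@requireStart) "ATG required;" else "start optional;",
      if (object@requireStop) "stop required\n" else "stop optional\n")
})

#' Ground truth of a simulated receptor family
#'
#' Records everything downstream inference is later asked to recover: the
#' gene tree over surviving gene copies, the true orthogroup of every copy,
#' the duplication/loss/pseudogenization events with the species-tree branch
#' they occurred on, and the transcript-variant labels assigned at emission.
#'
#' @slot geneTree rooted \code{phylo} over surviving gene copies (or NULL
#'   when fewer than two copies survive)
#' @slot speciesTree the species tree the family evolved along
#' @slot orthogroups named character vector: gene copy -> true orthogroup
#' @slot copySpecies named character vector: gene copy -> species
#' @slot events data.frame with columns \code{branch} (species-tree branch,
#'   named by its child node) and \code{kind} (duplication, loss,
#'   pseudogenization)
#' @slot variantLabels named character vector: transcript id -> one of
#'   primary, same_peptide_variant, truncated_variant, end_modified_variant
#'   (filled by \code{\link{emitTranscripts}})
#' @slot nodeBranch named character vector: gene-tree node label ->
#'   species-tree branch (child-node name) on which the node sits
#' @slot params the \code{SimParams} used
#' @export
setClass("TruthRecord", representation(
  geneTree = "ANY",
  speciesTree = "phylo",
  orthogroups = "character",
  copySpecies = "character",
  events = "data.frame",
  variantLabels = "character",
  nodeBranch = "character",
  params = "SimParams"
))

setValidity("TruthRecord", function(object) {
  msg <- character()
  if (length(object@orthogroups) != length(object@copySpecies))
    msg <- c(msg, "orthogroups and copySpecies must cover the same copies")
  okBranch <- c(object@speciesTree$tip.label,
                as.character(seq_len(object@speciesTree$Nnode) +
                               length(object@speciesTree$tip.label)))
  if (nrow(object@events) && !all(object@events$branch %in% okBranch))
    msg <- c(msg, "event branches must exist in the species tree")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthRecord", function(object) {
  cat("TruthRecord:", length(object@orthogroups), "surviving gene copies in",
      length(unique(object@orthogroups)), "true orthogroups across",
      length(unique(object@copySpecies)), "species\n")
  if (nrow(object@events))
    print(table(object@events$kind))
  else cat("  no events\n")
})

#' Accessors for TruthRecord
#'
#' @param x a \code{\linkS4class{TruthRecord}}
#' @return \code{trueOrthogroups}: named character vector of gene copy ->
#'   orthogroup; \code{truthEvents}: the event data.frame; \code{geneTree}:
#'   the gene \code{phylo}; \code{variantLabels}: named character vector of
#'   transcript labels.
#' @name TruthRecord-accessors
NULL

#' @rdname TruthRecord-accessors
#' @export
trueOrthogroups <- function(x) x@orthogroups

#' @rdname TruthRecord-accessors
#' @export
truthEvents <- function(x) x@events

#' @rdname TruthRecord-accessors
#' @export
geneTree <- function(x) x@geneTree

#' @rdname TruthRecord-accessors
#' @export
variantLabels <- function(x) x@variantLabels

#' A set of delimited orthogroups
#'
#' Wraps the per-orthogroup table (name, species set, reference genes,
#' orthology category, clade) together with the member leaves of each group.
#'
#' @slot table data.frame with one row per orthogroup: \code{name},
#'   \code{n_members}, \code{n_species}, \code{species_set} (comma-joined),
#'   \code{reference_genes} (comma-joined), \code{category}, \code{clade}
#' @slot members named list of character vectors of member leaf labels,
#'   parallel to \code{table$name}
#' @export
setClass("OrthogroupSet", representation(
  table = "data.frame", members = "list"
))

setValidity("OrthogroupSet", function(object) {
  msg <- character()
  if (nrow(object@table) != length(object@members))
    msg <- c(msg, "one member vector per table row required")
  if (any(lengths(object@members) == 0L))
    msg <- c(msg, "orthogroups must have at least one member")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrthogroupSet", function(object) {
  cat("OrthogroupSet:", nrow(object@table), "orthogroups,",
      sum(lengths(object@members)), "member leaves\n")
  if (nrow(object@table)) print(table(object@table$category))
})

#' @param x an \code{OrthogroupSet}
#' @return \code{ogTable}: the per-orthogroup data.frame; \code{ogMembers}:
#'   the named list of member leaf labels.
#' @rdname OrthogroupSet-class
#' @export
ogTable <- function(x) x@table

#' @rdname OrthogroupSet-class
#' @export
ogMembers <- function(x) x@members

setMethod("length", "OrthogroupSet", function(x) nrow(x@table))
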