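#' Emit transcript FASTA records from a simulated family
#'
#' Every surviving gene copy emits one primary transcript (its codon
#' sequence plus a TAA terminator, id \code{<species>|g<gene>|t1}). With
#' probability \code{pVariant} an extra transcript is emitted and labelled
#' in the truth table with the sampled class:
#' \describe{
#'   \item{same_peptide}{\code{synVariantChanges} random synonymous
#'     substitutions, so the DNA differs but the peptide is identical;}
#'   \item{truncated}{the first \code{(1 - truncFrac)} fraction of the
#'     codons, re-terminated (one-exon truncation emulation);}
#'   \item{end_modified}{the last \code{endModCodons} codons resampled to
#'     distinct sense codons.}
#' }
#' Pseudogenized copies were never turned into gene copies by the simulator
#' and therefore emit nothing.
#'
#' @param truth a \code{\linkS4class{TruthRecord}}; its
#'   \code{variantLabels} slot is filled in the returned copy
#' @param sequences named codon sequences from \code{\link{evolveSequences}}
#' @param params the \code{SimParams} in force
#' @return list with \code{fasta}: named list of \code{DNAStringSet}, one
#'   per species; \code{truth}: the updated \code{TruthRecord};
#'   \code{table}: data.frame (transcript, species, gene, orthogroup,
#'   variant_label)
#' @export
emitTranscripts <- function(truth, sequences, params = truth@params) {
  set.seed(params@seed + 2L)
  genes <- names(truth@orthogroups)
  labels <- character()
  seqsOut <- character()
  species <- character()
  geneOf <- character()
  vlab <- character()
  for (g in genes) {
    sp <- truth@copySpecies[[g]]
    tip <- paste0(sp, "|", g, "|t1")
    cds <- sequences[[tip]]
    if (is.null(cds) || is.na(cds))
      stop("no sequence available for surviving copy ", tip)
    labels <- c(labels, tip)
    seqsOut <- c(seqsOut, paste0(cds, "TAA"))
    species <- c(species, sp)
    geneOf <- c(geneOf, g)
    vlab[tip] <- "primary"
    if (stats::runif(1) < params@pVariant) {
      cls <- sample(names(params@variantWeights), 1L,
                    prob = params@variantWeights)
      vcds <- switch(cls,
        same_peptide = .synMutate(cds, params@synVariantChanges),
        truncated = .truncateCds(cds, params@truncFrac),
        end_modified = .endModify(cds, params@endModCodons))
      vid <- paste0(sp, "|", g, "|t2")
      labels <- c(labels, vid)
      seqsOut <- c(seqsOut, paste0(vcds, "TAA"))
      species <- c(species, sp)
      geneOf <- c(geneOf, g)
      vlab[vid] <- paste0(cls, "_variant")
    }
  }
  fasta <- list()
  for (sp in unique(species)) {
    idx <- species == sp
    ss <- Biostrings::DNAStringSet(seqsOut[idx])
    names(ss) <- labels[idx]
    fasta[[sp]] <- ss
  }
  truth@variantLabels <- vlab
  tab <- data.frame(transcript = labels, species = species, gene = geneOf,
                    orthogroup = unname(truth@orthogroups[geneOf]),
                    variant_label = unname(vlab[labels]),
                    stringsAsFactors = FALSE)
  list(fasta = fasta, truth = truth, table = tab)
}

# k random synonymous single-nucleotide substitutions (positions with a
# synonymous alternative only; initiator codon excluded).
.synMutate <- function(cds, k) {
  cods <- .splitCodons(cds)
  elig <- which(vapply(cods, function(cc) {
    nb <- .codonNeighbours[[cc]]
    any(nb$syn & !nb$stop)
  }, logical(1)))
  elig <- setdiff(elig, 1L)
  if (!length(elig)) return(cds)
  pick <- sample(elig, min(k, length(elig)))
  for (i in pick) {
    nb <- .codonNeighbours[[cods[i]]]
    nb <- nb[nb$syn & !nb$stop, , drop = FALSE]
    cods[i] <- nb$to[sample.int(nrow(nb), 1L)]
  }
  paste(cods, collapse = "")
}

.truncateCds <- function(cds, truncFrac) {
  cods <- .splitCodons(cds)
  keep <- round((1 - truncFrac) * length(cods))
  keep <- max(keep, 2L)
  paste(cods[seq_len(keep)], collapse = "")
}

# Resample the last m codons to different sense codons (peptide-changing at
# the C-terminal end).
.endModify <- function(cds, m) {
  cods <- .splitCodons(cds)
  L <- length(cods)
  idx <- seq.int(max(2L, L - m + 1L), L)
  for (i in idx) {
    alt <- setdiff(.codonTable$sense, cods[i])
    # force an amino-acid change so the variation is visible in peptides
    aaDiff <- alt[.translateCodons(alt) != .translateCodons(cods[i])]
    cods[i] <- sample(aaDiff, 1L)
  }
  paste(cods, collapse = "")
}

#' Write the simulator's outputs to a directory
#'
#' Emits per-species FASTA (60-column wrap), the gene tree in newick, and
#' tab-delimited truth tables (orthogroups, events, variant labels).
#'
#' @param emitted result of \code{\link{emitTranscripts}}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSimulation <- function(emitted, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sp in names(emitted$fasta)) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(emitted$fasta[[sp]], p, width = 60L)
    paths <- c(paths, p)
  }
  truth <- emitted$truth
  if (!is.null(truth@geneTree)) {
    p <- file.path(dir, "gene_tree.nwk")
    ape::write.tree(truth@geneTree, p)
    paths <- c(paths, p)
  }
  og <- data.frame(gene = names(truth@orthogroups),
                   orthogroup = unname(truth@orthogroups),
                   species = unname(truth@copySpecies))
  writeTsv(og, file.path(dir, "truth_orthogroups.tsv"))
  writeTsv(truth@events, file.path(dir, "truth_events.tsv"))
  writeTsv(emitted$table, file.path(dir, "truth_transcripts.tsv"))
  invisible(c(paths, file.path(dir, c("truth_orthogroups.tsv",
                                      "truth_events.tsv",
                                      "truth_transcripts.tsv"))))
}
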