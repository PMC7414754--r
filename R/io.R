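#' Tab-delimited table I/O
#'
#' Plain TSV with a header row, UTF-8, '.' decimal separator, no quoting
#' of simple fields; empty strings survive a round-trip distinct from
#' zeros.
#'
#' @param x data.frame to write
#' @param path file path
#' @return \code{readTsv}: a data.frame; \code{writeTsv}: the path,
#'   invisibly
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "", na.strings = NULL,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  # convert columns without empty fields; empty strings stay distinct
  # from zeros
  for (j in seq_along(x)) {
    if (any(x[[j]] == "")) next
    x[[j]] <- utils::type.convert(x[[j]], as.is = TRUE,
                                  na.strings = character())
  }
  x
}

#' Read / write FASTA (wrap-agnostic read, 60-column write)
#'
#' Thin wrappers over Biostrings so every module shares one dialect.
#'
#' @param path file path
#' @param type \code{"DNA"} or \code{"AA"}
#' @return \code{readFasta}: a named character vector
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' @param seqs named character vector
#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Newick tree I/O with position-reporting parse errors
#'
#' @param path newick file (quoted labels and bootstrap node labels
#'   supported via ape)
#' @return \code{readNewick}: a \code{phylo}
#' @export
readNewick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    bal <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
    pos <- if (any(bal < 0)) which(bal < 0)[1] else nchar(txt)
    stop("malformed newick in ", path, " near character ", pos)
  }
  tr
}

#' @param tree a \code{phylo}
#' @rdname readNewick
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Thread a codon sequence through a gapped peptide row
#'
#' Expands each peptide alignment column into three nucleotide columns
#' (gap columns become \code{---}), producing in-frame codon alignments
#' from peptide alignments.
#'
#' @param pepAligned gapped peptide row
#' @param cds the ungapped coding sequence (terminator excluded or
#'   included; a trailing terminator is dropped)
#' @return the gapped codon row
#' @export
threadCodons <- function(pepAligned, cds) {
  cods <- .splitCodons(cds)
  if (length(cods) && cods[length(cods)] %in% .STOP_CODONS)
    cods <- cods[-length(cods)]
  chars <- strsplit(pepAligned, "")[[1]]
  nres <- sum(chars != "-")
  if (nres != length(cods))
    stop("peptide row has ", nres, " residues but cds has ",
         length(cods), " codons")
  out <- character(length(chars))
  k <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") out[i] <- "---"
    else { k <- k + 1L; out[i] <- cods[k] }
  }
  paste(out, collapse = "")
}

#' Translate a coding sequence to peptide
#'
#' @param cds DNA string with length a codon multiple
#' @param stripStop drop a trailing terminator codon before translating
#' @return peptide string
#' @export
translateCds <- function(cds, stripStop = TRUE) {
  cods <- .splitCodons(cds)
  if (stripStop && length(cods) && cods[length(cods)] %in% .STOP_CODONS)
    cods <- cods[-length(cods)]
  paste(.translateCodons(cods), collapse = "")
}

#' Read / write the pipeline configuration
#'
#' Plain-text YAML key-value configuration. Every parameter has a default;
#' \code{readConfig} overlays the file on the defaults so a minimal file
#' is enough, and the resolved values round-trip losslessly through
#' \code{writeConfig}.
#'
#' @param path YAML file
#' @return named list of configuration blocks
#' @export
readConfig <- function(path) {
  user <- if (!is.null(path) && file.exists(path)) yaml::read_yaml(path)
  else list()
  .mergeConfig(defaultConfig(), user)
}

#' @param config configuration list
#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readConfig
#' @export
defaultConfig <- function() {
  list(
    species = c("domesticus", "spicilegus", "macedonicus", "spretus",
                "caroli", "pahari"),
    reference_species = "domesticus",
    focal_species = "domesticus",
    simulate = list(
      n_root_genes = 10L, dup_rate = 0.5, loss_rate = 0.4,
      pseudo_prob = 0.5, omega_default = 0.5, kappa = 2,
      gene_length = 300L, p_variant = 0.25,
      variant_weights = list(same_peptide = 0.6, truncated = 0.25,
                             end_modified = 0.15),
      trunc_frac = 0.4, root_to_tip = 0.07, seed = NULL),
    gene_model = list(min_len = 270L, max_len = 400L,
                      require_start = TRUE, require_stop = TRUE),
    identity_threshold = 30,
    identity_stat = "mean",
    dupvar = list(end_window = 10L, gap_window = 5L, trunc_frac = 0.75),
    selection = list(q = 0.05, scope = "pooled", min_members = 4L,
                     kappa = 1),
    min_support = 3L,
    min_bootstrap = 50,
    sites = list(short_len_frac = 0.8)
  )
}

.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

.simParamsFromConfig <- function(config) {
  s <- config$simulate
  if (is.null(s$seed))
    stop("simulate: an explicit seed is required in the configuration")
  SimParams(
    seed = s$seed, nRootGenes = s$n_root_genes, dupRate = s$dup_rate,
    lossRate = s$loss_rate, pseudoProb = s$pseudo_prob,
    omegaMap = c(default = s$omega_default), kappa = s$kappa,
    geneLength = s$gene_length, pVariant = s$p_variant,
    variantWeights = unlist(s$variant_weights),
    truncFrac = s$trunc_frac)
}
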