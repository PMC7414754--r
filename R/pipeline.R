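#' Derive a reference repertoire from a simulated truth
#'
#' The reference-species (house mouse) gene copies of a simulation play
#' the role of the annotated reference genome: each copy becomes a
#' reference gene \code{Vmn1r<n>} (n = the copy number), and every true
#' orthogroup is assigned a clade from the rotating 11-clade set so that
#' clade-level summaries are exercised.
#'
#' @param emitted result of \code{\link{emitTranscripts}}
#' @param referenceSpecies the species whose copies form the reference
#' @param clades clade labels to rotate over true orthogroups
#' @return list(peptides = named character vector (reference gene id ->
#'   peptide), cds = named character vector, cladeMap = named character
#'   vector (reference gene id -> clade), ogClade = named character vector
#'   (true orthogroup -> clade), refIds)
#' @export
referenceFromTruth <- function(emitted,
                               referenceSpecies = "domesticus",
                               clades = c("A/B", "C", "D", "E", "F", "G",
                                          "H", "I", "J/K", "L", "N")) {
  truth <- emitted$truth
  tab <- emitted$table
  ogAll <- sort(unique(unname(truth@orthogroups)))
  ogClade <- stats::setNames(rep(clades, length.out = length(ogAll)),
                             ogAll)
  ref <- tab[tab$species == referenceSpecies &
               tab$variant_label == "primary", , drop = FALSE]
  if (!nrow(ref))
    stop("no ", referenceSpecies, " copies survive; cannot build a ",
         "reference repertoire")
  ids <- paste0("Vmn1r", sub("^g", "", ref$gene))
  cds <- character(); pep <- character()
  for (i in seq_len(nrow(ref))) {
    s <- as.character(emitted$fasta[[referenceSpecies]][[ref$transcript[i]]])
    cods <- .splitCodons(s)
    if (cods[length(cods)] %in% .STOP_CODONS) cods <- cods[-length(cods)]
    cds[ids[i]] <- paste(cods, collapse = "")
    pep[ids[i]] <- paste(.translateCodons(cods), collapse = "")
  }
  cladeMap <- stats::setNames(unname(ogClade[ref$orthogroup]), ids)
  list(peptides = pep, cds = cds, cladeMap = cladeMap,
       ogClade = ogClade, refIds = ids)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages in their study order: receptor identification
#' (ORF extraction, deduplication, best-hit annotation, identity filter),
#' orthology (gene tree, species-overlap delimitation, grammar naming,
#' categories, clades), duplicate/variant classification, the selection
#' screen with FDR correction and clade aggregation, and repertoire
#' summaries (category fractions, clade sizes, loss calls,
#' reference-only concentration). With a \code{simulate} seed in the
#' configuration the inputs are generated by the simulator and the
#' reference repertoire is derived from the simulated house mouse;
#' otherwise transcript FASTA, reference FASTA and clade map paths must
#' be supplied under \code{config$inputs}. All artifacts are written to
#' \code{outDir} together with a JSON manifest of resolved parameters and
#' output checksums; a failed run removes its partial outputs.
#'
#' @param config configuration list from \code{\link{readConfig}}
#' @param outDir output directory
#' @return invisibly, a list with the main result objects (orthogroups,
#'   calls, tests, summaries, transcript table)
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(outDir, dir(outDir)),
                          recursive = TRUE), add = TRUE)
  res <- .runPipelineInner(config, outDir)
  manifest <- list(
    package = as.character(utils::packageVersion("v1rCladeEvo")),
    parameters = config,
    outputs = as.list(tools::md5sum(
      list.files(outDir, full.names = TRUE,
                 pattern = "\\.(tsv|fasta|nwk)$"))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(res)
}

.runPipelineInner <- function(config, outDir) {
  refSp <- config$reference_species
  gm <- GeneModel(config$gene_model$min_len, config$gene_model$max_len,
                  config$gene_model$require_start,
                  config$gene_model$require_stop)

  if (!is.null(config$simulate$seed)) {
    params <- .simParamsFromConfig(config)
    speciesTree <- musSpeciesTree(config$simulate$root_to_tip)
    truth <- simulateFamily(speciesTree, params)
    seqs <- evolveSequences(truth, params)
    emitted <- emitTranscripts(truth, seqs, params)
    writeSimulation(emitted, file.path(outDir, "sim"))
    ref <- referenceFromTruth(emitted, refSp)
    fasta <- emitted$fasta
  } else {
    inp <- config$inputs
    for (p in c(unlist(inp$transcripts), inp$reference_fasta,
                inp$clade_map))
      if (!file.exists(p)) stop("missing input: ", p)
    fasta <- lapply(inp$transcripts, function(p)
      Biostrings::DNAStringSet(readFasta(p, "DNA")))
    refCds <- readFasta(inp$reference_fasta, "DNA")
    pep <- vapply(refCds, function(s) {
      cods <- .splitCodons(s)
      if (cods[length(cods)] %in% .STOP_CODONS)
        cods <- cods[-length(cods)]
      paste(.translateCodons(cods), collapse = "")
    }, character(1))
    cm <- readTsv(inp$clade_map)
    ref <- list(peptides = pep, cds = refCds,
                cladeMap = stats::setNames(cm$clade, cm$gene),
                refIds = names(refCds))
    truth <- NULL
  }

  # --- receptor mining per sequenced (non-reference) species ---
  mined <- list()
  for (sp in setdiff(names(fasta), refSp)) {
    m <- mineReceptors(fasta[[sp]], ref$peptides, gm,
                       threshold = config$identity_threshold,
                       species = sp)
    if (nrow(m)) mined[[sp]] <- m
  }
  minedAll <- if (length(mined)) do.call(rbind, mined)
  else stop("no receptors recovered from any species")
  rownames(minedAll) <- NULL
  minedAll <- annotateTranscripts(minedAll)
  writeTsv(minedAll[, c("id", "species", "ref", "hit_score",
                        "hit_identity", "annotation")],
           file.path(outDir, "mined_transcripts.tsv"))

  # --- gene tree over mined peptides + reference repertoire ---
  pep <- c(stats::setNames(minedAll$peptide, minedAll$id), ref$peptides)
  tree <- if (!is.null(config$inputs$gene_tree))
    readNewick(config$inputs$gene_tree)
  else buildGeneTree(pep)
  leafInfo <- data.frame(
    label = names(pep),
    species = c(minedAll$species, rep(refSp, length(ref$peptides))),
    refGene = c(rep(NA_character_, nrow(minedAll)), names(ref$peptides)),
    stringsAsFactors = FALSE)
  ogs <- delimitOrthogroups(tree, leafInfo,
                            minSupport = config$min_bootstrap,
                            referenceSpecies = refSp)
  ogs <- nameOrthogroups(ogs, tree, leafInfo)
  ogs <- assignClades(ogs, ref$cladeMap, tree, leafInfo)
  writeTsv(ogTable(ogs), file.path(outDir, "orthogroups.tsv"))

  # orthogroup/category/clade of every leaf
  leafOg <- stats::setNames(
    rep(ogTable(ogs)$name, lengths(ogMembers(ogs))),
    unlist(ogMembers(ogs)))
  ogRow <- match(unname(leafOg), ogTable(ogs)$name)
  leafCat <- stats::setNames(ogTable(ogs)$category[ogRow], names(leafOg))
  leafClade <- stats::setNames(ogTable(ogs)$clade[ogRow], names(leafOg))

  transcripts <- data.frame(
    transcript = c(minedAll$id, names(ref$peptides)),
    species = c(minedAll$species, rep(refSp, length(ref$peptides))),
    annotation = c(minedAll$annotation, names(ref$peptides)),
    orthogroup = unname(leafOg[c(minedAll$id, names(ref$peptides))]),
    category = unname(leafCat[c(minedAll$id, names(ref$peptides))]),
    clade = unname(leafClade[c(minedAll$id, names(ref$peptides))]),
    stringsAsFactors = FALSE)
  writeTsv(transcripts, file.path(outDir, "transcripts.tsv"))

  # --- duplicate / variant classification ---
  pepOf <- pep
  dv <- config$dupvar
  calls <- list()
  for (og in ogTable(ogs)$name) {
    mem <- ogMembers(ogs)[[og]]
    spOf <- stats::setNames(leafInfo$species, leafInfo$label)[mem]
    for (sp in unique(spOf)) {
      ids <- mem[spOf == sp]
      if (length(ids) < 2L) next
      cl <- classifySpeciesSet(pepOf[ids], dv$end_window, dv$gap_window,
                               dv$trunc_frac)
      if (nrow(cl)) {
        cl$species <- sp
        cl$orthogroup <- og
        cl$clade <- ogTable(ogs)$clade[match(og, ogTable(ogs)$name)]
        calls[[length(calls) + 1L]] <- cl
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls)
  else data.frame(transcript = character(), partner = character(),
                  verdict = character(), rule = character(),
                  end_window = numeric(), gap_window = numeric(),
                  species = character(), orthogroup = character(),
                  clade = character(), stringsAsFactors = FALSE)
  writeTsv(calls, file.path(outDir, "dupvar_calls.tsv"))
  writeTsv(summarizeDupVar(calls), file.path(outDir,
                                             "dupvar_summary.tsv"))

  # --- selection screen ---
  selCfg <- config$selection
  tests <- if (!is.null(config$inputs$external_tests)) {
    ingestExternalTests(config$inputs$external_tests)
  } else {
    cdsOf <- c(stats::setNames(minedAll$cds, minedAll$id), ref$cds)
    elig <- eligibleOrthogroups(ogs, selCfg$min_members)
    tl <- list()
    for (og in ogTable(elig)$name) {
      mem <- ogMembers(elig)[[og]]
      msa <- centerStarAlign(pepOf[mem])
      codAln <- vapply(mem, function(id)
        threadCodons(msa[[id]], cdsOf[[id]]), character(1))
      sub <- ape::keep.tip(tree, mem)
      t1 <- try(branchDndsScreen(codAln, sub, orthogroup = og,
                                 kappa = selCfg$kappa), silent = TRUE)
      if (!inherits(t1, "try-error") && nrow(t1))
        tl[[length(tl) + 1L]] <- t1
    }
    if (length(tl)) do.call(rbind, tl)
    else data.frame(orthogroup = character(), branch = character(),
                    branch_kind = character(), p_raw = numeric(),
                    source = character(), stringsAsFactors = FALSE)
  }
  tests <- fdrCorrect(tests, q = selCfg$q, scope = selCfg$scope)
  writeTsv(tests, file.path(outDir, "branch_tests.tsv"))
  selSummary <- summarizeSelection(
    tests, stats::setNames(ogTable(ogs)$clade, ogTable(ogs)$name))
  writeTsv(selSummary, file.path(outDir, "selection_summary.tsv"))

  # --- turnover summaries ---
  fr <- categoryFractions(transcripts)
  writeTsv(fr, file.path(outDir, "category_fractions.tsv"))
  cs <- cladeSizes(transcripts, "unique")
  writeTsv(cs, file.path(outDir, "clade_sizes.tsv"))
  losses <- callLosses(ogs, config$focal_species, config$species,
                       ref$refIds, minSupport = config$min_support)
  writeTsv(losses, file.path(outDir, "loss_calls.tsv"))
  conc <- referenceOnlyConcentration(ogs)

  list(orthogroups = ogs, transcripts = transcripts, dupvarCalls = calls,
       tests = tests, selectionSummary = selSummary,
       categoryFractions = fr, cladeSizes = cs, losses = losses,
       referenceOnlyConcentration = conc,
       truth = if (exists("truth")) truth else NULL)
}
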