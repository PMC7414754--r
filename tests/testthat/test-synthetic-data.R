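test_that("no-event limit gives one complete orthogroup per root gene", {
  tr <- musSpeciesTree()
  p <- SimParams(seed = 5L, nRootGenes = 5L, dupRate = 0, lossRate = 0)
  truth <- simulateFamily(tr, p)
  og <- trueOrthogroups(truth)
  expect_length(unique(og), 5L)
  expect_true(all(table(og) == 6L))
  sp <- truth@copySpecies
  for (g in unique(og))
    expect_setequal(unname(sp[names(og)[og == g]]), tr$tip.label)
  expect_identical(nrow(truthEvents(truth)), 0L)
})

test_that("parameter validation rejects bad rates and weights", {
  expect_error(SimParams(seed = 1L, dupRate = -1), "nonnegative")
  expect_error(SimParams(seed = 1L, geneLength = 50L), "100 codons")
  expect_error(SimParams(seed = 1L,
                         variantWeights = c(same_peptide = 0.5,
                                            truncated = 0.5,
                                            end_modified = 0.5)),
               "sum to 1")
  expect_error(SimParams(), "seed")
})

test_that("zero-length branches with positive rates produce no events", {
  tr <- musSpeciesTree()
  tr$edge.length[] <- 0
  p <- SimParams(seed = 2L, nRootGenes = 3L, dupRate = 5, lossRate = 5)
  truth <- simulateFamily(tr, p)
  expect_identical(nrow(truthEvents(truth)), 0L)
  expect_length(trueOrthogroups(truth), 18L)
})

test_that("identical seed and params give byte-identical outputs", {
  tr <- musSpeciesTree()
  p <- SimParams(seed = 31L, nRootGenes = 4L)
  run <- function() {
    truth <- simulateFamily(tr, p)
    seqs <- evolveSequences(truth, p)
    em <- emitTranscripts(truth, seqs, p)
    d <- withr::local_tempdir()
    writeSimulation(em, d)
    lapply(sort(dir(d)), function(f)
      readLines(file.path(d, f), warn = FALSE))
  }
  expect_identical(run(), run())
})

test_that("gene-tree nodes map onto species-tree branches", {
  tr <- musSpeciesTree()
  p <- SimParams(seed = 9L, nRootGenes = 6L, dupRate = 0.8, lossRate = 0.5)
  truth <- simulateFamily(tr, p)
  valid <- c(tr$tip.label,
             as.character(length(tr$tip.label) + seq_len(tr$Nnode)))
  expect_true(all(truth@nodeBranch %in% valid))
  gt <- geneTree(truth)
  if (!is.null(gt)) {
    labs <- c(gt$tip.label, gt$node.label)
    expect_true(all(labs %in% names(truth@nodeBranch)))
    # tips sit on the branch of their own species
    for (tp in gt$tip.label)
      expect_identical(unname(truth@nodeBranch[tp]),
                       strsplit(tp, "|", fixed = TRUE)[[1]][1])
  }
})

test_that("pure-birth copy number matches the exponential mean", {
  tr <- ape::read.tree(text = "(A:1,B:0);")
  lam <- 0.6
  n <- vapply(1:2000, function(s) {
    p <- SimParams(seed = s, nRootGenes = 1L, dupRate = lam, lossRate = 0)
    sum(simulateFamily(tr, p)@copySpecies == "A")
  }, numeric(1))
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(lam)), 3 * se)
})

test_that("pure death only removes species from orthogroups", {
  tr <- musSpeciesTree()
  for (s in 1:20) {
    p <- SimParams(seed = 100L + s, nRootGenes = 4L, dupRate = 0,
                   lossRate = 3)
    truth <- simulateFamily(tr, p)
    og <- trueOrthogroups(truth)
    expect_lte(length(unique(og)), 4L)
    # without duplication no species holds two copies of one orthogroup
    if (length(og))
      expect_false(any(duplicated(paste(og,
                                        truth@copySpecies[names(og)]))))
    expect_true(all(truth@copySpecies %in% tr$tip.label))
  }
})

test_that("sequence evolution respects branch length zero and omega zero", {
  tr <- ape::read.tree(text = "(A:0,B:0.3);")
  p <- SimParams(seed = 3L, nRootGenes = 1L, dupRate = 0, lossRate = 0,
                 omegaMap = c(default = 0), geneLength = 150L)
  truth <- simulateFamily(tr, p)
  seqs <- evolveSequences(truth, p)
  tipA <- grep("^A\\|", names(seqs), value = TRUE)
  tipB <- grep("^B\\|", names(seqs), value = TRUE)
  rootLab <- setdiff(names(seqs), c(tipA, tipB))
  # zero branch: identical to the parent (the root)
  expect_identical(seqs[[tipA]], seqs[[rootLab[1]]])
  # omega = 0: peptide conserved even across the long branch
  expect_identical(translateCds(seqs[[tipB]], stripStop = FALSE),
                   translateCds(seqs[[rootLab[1]]], stripStop = FALSE))
  expect_false(identical(seqs[[tipB]], seqs[[rootLab[1]]]))
  expect_error(evolveSequences(truth, p, rootSequence = "ATGTAA"),
               "stop")
})

test_that("neutral evolution yields counting dN/dS near one", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  ratio <- vapply(1:200, function(s) {
    p <- SimParams(seed = s, nRootGenes = 1L, dupRate = 0, lossRate = 0,
                   omegaMap = c(default = 1), kappa = 1,
                   geneLength = 300L)
    truth <- simulateFamily(tr, p)
    sq <- evolveSequences(truth, p)
    tips <- grep("\\|g", names(sq), value = TRUE)
    tr2 <- tr
    tr2$tip.label <- tips[match(c("A", "B"), sub("\\|.*", "", tips))]
    bt <- branchDndsScreen(sq[tr2$tip.label], tr2, kappa = 1)
    (sum(bt$nd) / sum(bt$n_nonsyn_sites)) /
      (sum(bt$sd) / sum(bt$n_syn_sites))
  }, numeric(1))
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("transcript emission obeys the variant construction rules", {
  tr <- musSpeciesTree()
  # no variants: one transcript per surviving copy
  p0 <- SimParams(seed = 8L, nRootGenes = 3L, pVariant = 0)
  t0 <- simulateFamily(tr, p0)
  em0 <- emitTranscripts(t0, evolveSequences(t0, p0), p0)
  expect_identical(nrow(em0$table), length(trueOrthogroups(t0)))
  expect_true(all(em0$table$variant_label == "primary"))

  # same-peptide variants translate identically to their primary
  p1 <- SimParams(seed = 8L, nRootGenes = 3L, pVariant = 1,
                  variantWeights = c(same_peptide = 1, truncated = 0,
                                     end_modified = 0))
  t1 <- simulateFamily(tr, p1)
  em1 <- emitTranscripts(t1, evolveSequences(t1, p1), p1)
  v <- em1$table[em1$table$variant_label == "same_peptide_variant", ]
  expect_gt(nrow(v), 0L)
  for (i in seq_len(nrow(v))) {
    sp <- v$species[i]
    prim <- sub("\\|t2$", "|t1", v$transcript[i])
    a <- as.character(em1$fasta[[sp]][[v$transcript[i]]])
    b <- as.character(em1$fasta[[sp]][[prim]])
    expect_false(identical(a, b))           # DNA differs
    expect_identical(translateCds(a), translateCds(b))
  }

  # truncation arithmetic: 0.4 removed from 300 codons leaves 180
  p2 <- SimParams(seed = 8L, nRootGenes = 2L, pVariant = 1,
                  variantWeights = c(same_peptide = 0, truncated = 1,
                                     end_modified = 0),
                  truncFrac = 0.4, geneLength = 300L)
  t2 <- simulateFamily(tr, p2)
  em2 <- emitTranscripts(t2, evolveSequences(t2, p2), p2)
  v2 <- em2$table[em2$table$variant_label == "truncated_variant", ]
  expect_gt(nrow(v2), 0L)
  for (i in seq_len(nrow(v2))) {
    cds <- as.character(em2$fasta[[v2$species[i]]][[v2$transcript[i]]])
    expect_identical(nchar(cds) / 3 - 1, 180)  # +1 codon for terminator
  }

  # pseudogenized copies never emit: every emitted gene is a survivor
  p3 <- SimParams(seed = 12L, nRootGenes = 5L, lossRate = 2,
                  pseudoProb = 1)
  t3 <- simulateFamily(tr, p3)
  em3 <- emitTranscripts(t3, evolveSequences(t3, p3), p3)
  expect_true(all(em3$table$gene %in% names(trueOrthogroups(t3))))
})
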