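makeOgSet <- function(df, membersList = NULL) {
  # df: name, species_set (comma-joined), clade, optional reference_genes
  if (is.null(df$reference_genes)) df$reference_genes <- ""
  tab <- data.frame(
    name = df$name, n_members = NA_integer_,
    n_species = vapply(strsplit(df$species_set, ","), length,
                       integer(1)),
    species_set = df$species_set, reference_genes = df$reference_genes,
    category = NA_character_, clade = df$clade, stringsAsFactors = FALSE)
  if (is.null(membersList))
    membersList <- lapply(seq_len(nrow(tab)), function(i)
      paste0(tab$name[i], "_m",
             seq_len(max(1L, tab$n_species[i]))))
  names(membersList) <- tab$name
  tab$n_members <- lengths(membersList)
  categorizeOrthogroups(new("OrthogroupSet", table = tab,
                            members = membersList))
}

test_that("clade sizes count unique annotations and keep unplaced", {
  tx <- data.frame(
    species = c("spretus", "spretus", "spretus", "caroli", "caroli"),
    annotation = c("Vmn1r5.1", "Vmn1r5.2", "Vmn1r9", "Vmn1r5", "x1"),
    clade = c("C", "C", "D", "C", NA), stringsAsFactors = FALSE)
  uq <- cladeSizes(tx, "unique")
  expect_identical(uq$spretus[uq$clade == "C"], 1L)
  expect_identical(uq$spretus[uq$clade == "D"], 1L)
  expect_identical(uq$caroli[uq$clade == "unplaced"], 1L)
  tot <- cladeSizes(tx, "total")
  expect_identical(tot$spretus[tot$clade == "C"], 2L)
  # column sums equal repertoire sizes per species
  expect_identical(sum(tot$caroli), 2L)
  expect_identical(sum(tot$spretus), 3L)
})

test_that("category fractions sum to 100 on both bases", {
  tx <- data.frame(
    species = rep("spretus", 4),
    annotation = paste0("Vmn1r", 1:4),
    category = c("reference_only", "non_orthologous", "low_orthology",
                 "high_orthology"), stringsAsFactors = FALSE)
  fr <- categoryFractions(tx)
  expect_equal(fr$pct_unique, rep(25, 4))
  expect_equal(fr$pct_total, rep(25, 4))
  all.high <- data.frame(species = "caroli",
                         annotation = paste0("Vmn1r", 1:7),
                         category = "high_orthology")
  fh <- categoryFractions(all.high)
  expect_equal(fh$pct_total[fh$category == "high_orthology"], 100)
  expect_equal(sum(fh$pct_total), 100)
  # suffix variants collapse on the unique basis only
  tx2 <- data.frame(
    species = "spretus",
    annotation = c("Vmn1r1.1", "Vmn1r1.2", "Vmn1r2"),
    category = c("high_orthology", "high_orthology", "low_orthology"))
  f2 <- categoryFractions(tx2)
  expect_equal(f2$pct_unique[f2$category == "high_orthology"], 50)
  expect_equal(f2$pct_total[f2$category == "high_orthology"],
               100 * 2 / 3)
})

test_that("non-orthologous and low-orthology mass grows with loss rate", {
  tr <- musSpeciesTree()
  frac <- vapply(c(0.5, 2, 5), function(mu) {
    lost <- 0; tot <- 0
    for (s in 1:25) {
      p <- SimParams(seed = 700L + s, nRootGenes = 6L, dupRate = 0,
                     lossRate = mu)
      truth <- simulateFamily(tr, p)
      og <- trueOrthogroups(truth)
      sizes <- table(og)  # one copy per species when dupRate = 0
      tot <- tot + length(sizes)
      lost <- lost + sum(sizes <= 3)
    }
    lost / max(tot, 1)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("loss calling follows the support rule and allocates fresh ids", {
  ogs <- makeOgSet(data.frame(
    name = c("g1", "g2", "g3", "g4"),
    species_set = c("caroli,macedonicus,spicilegus",      # lost, 3 carriers
                    "caroli,spicilegus",                  # only 2 carriers
                    "domesticus,spicilegus,spretus",      # focal present
                    "caroli,macedonicus,pahari,spicilegus,spretus"),
    clade = c("C", "C", "D", "E"), stringsAsFactors = FALSE))
  allSp <- c("domesticus", "spicilegus", "macedonicus", "spretus",
             "caroli", "pahari")
  refs <- c("Vmn1r3", "Vmn1r250")
  calls <- callLosses(ogs, "domesticus", allSp, refs, minSupport = 3)
  expect_setequal(calls$orthogroup, c("g1", "g4"))
  expect_identical(calls$new_id, c("Vmn1r251", "Vmn1r252"))
  expect_false(any(calls$new_id %in% refs))
  # support sweep is nested
  c2 <- callLosses(ogs, "domesticus", allSp, refs, minSupport = 2)
  c4 <- callLosses(ogs, "domesticus", allSp, refs, minSupport = 4)
  expect_true(all(calls$orthogroup %in% c2$orthogroup))
  expect_true(all(c4$orthogroup %in% calls$orthogroup))
  # pseudogene cross-reference
  pg <- data.frame(orthogroup = "g1", pseudogene = "Vmn1r-ps40")
  cp <- callLosses(ogs, "domesticus", allSp, refs, pseudogeneTable = pg)
  expect_identical(cp$pseudogene[cp$orthogroup == "g1"], "Vmn1r-ps40")
  expect_error(callLosses(ogs, "rattus", allSp, refs), "not in the")
  # loss calls never overlap reference-only groups
  expect_false(any(ogTable(ogs)$category[match(calls$orthogroup,
                                               ogTable(ogs)$name)] ==
                     "reference_only"))
})

test_that("forced focal losses with enough carriers are all recalled", {
  tr <- musSpeciesTree()
  allSp <- tr$tip.label
  for (s in 1:40) {
    p <- SimParams(seed = 900L + s, nRootGenes = 5L, dupRate = 0,
                   lossRate = 1.5)
    truth <- simulateFamily(tr, p)
    og <- trueOrthogroups(truth)
    if (!length(og)) next
    spl <- split(unname(truth@copySpecies[names(og)]), unname(og))
    df <- data.frame(
      name = names(spl),
      species_set = vapply(spl, function(x)
        paste(sort(unique(x)), collapse = ","), character(1)),
      clade = "C", stringsAsFactors = FALSE)
    members <- lapply(names(spl), function(g)
      names(og)[og == g])
    ogs <- makeOgSet(df, members)
    want <- names(spl)[vapply(spl, function(x) {
      !"domesticus" %in% x &&
        length(intersect(x, setdiff(allSp, "domesticus"))) >= 3
    }, logical(1))]
    got <- callLosses(ogs, "domesticus", allSp, "Vmn1r1")
    expect_setequal(got$orthogroup, want)
  }
})

test_that("reference-only concentration reproduces modal arithmetic", {
  # 50 of 53 in one clade -> 94 percent
  ogs <- makeOgSet(data.frame(
    name = paste0("r", 1:53),
    species_set = "domesticus",
    clade = c(rep("D", 50), "C", "E", "G"), stringsAsFactors = FALSE))
  got <- referenceOnlyConcentration(ogs)
  expect_identical(got$n_reference_only, 53L)
  expect_identical(got$modal_clade, "D")
  expect_equal(got$percent, 94)
  # all in one clade -> 100
  one <- makeOgSet(data.frame(name = paste0("r", 1:7),
                              species_set = "domesticus", clade = "D"))
  expect_equal(referenceOnlyConcentration(one)$percent, 100)
  # uniform over 11 clades, 22 groups -> modal percent 9
  unif <- makeOgSet(data.frame(
    name = paste0("r", 1:22), species_set = "domesticus",
    clade = rep(c("A/B", "C", "D", "E", "F", "G", "H", "I", "J/K", "L",
                  "N"), 2)))
  expect_equal(referenceOnlyConcentration(unif)$percent, 9)
  # no reference-only groups -> not applicable
  none <- makeOgSet(data.frame(name = "x",
                               species_set = "caroli,spretus,pahari",
                               clade = "C"))
  expect_true(is.na(referenceOnlyConcentration(none)$percent))
})
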