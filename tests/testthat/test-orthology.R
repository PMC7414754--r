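test_that("annotation suffixes follow score order and stay stable", {
  h <- data.frame(id = c("tB", "tA"), species = "spretus",
                  ref = "Vmn1r30", hit_score = c(50, 90),
                  stringsAsFactors = FALSE)
  got <- annotateTranscripts(h)
  expect_identical(got$annotation[got$id == "tA"], "Vmn1r30.1")
  expect_identical(got$annotation[got$id == "tB"], "Vmn1r30.2")
  # single transcript keeps the bare id
  h1 <- data.frame(id = "t1", species = "caroli", ref = "Vmn1r7",
                   hit_score = 10)
  expect_identical(annotateTranscripts(h1)$annotation, "Vmn1r7")
  # equal scores: suffixes by id order, identical across runs
  h3 <- data.frame(id = c("c", "a", "b"), species = "caroli",
                   ref = "Vmn1r9", hit_score = 7)
  g3 <- annotateTranscripts(h3)
  expect_identical(g3$annotation[order(g3$id)],
                   c("Vmn1r9.1", "Vmn1r9.2", "Vmn1r9.3"))
  expect_identical(annotateTranscripts(h3), g3)
})

leafTable <- function(labels, species, refGene = NA_character_) {
  data.frame(label = labels, species = species,
             refGene = rep_len(refGene, length(labels)),
             stringsAsFactors = FALSE)
}

test_that("species-overlap delimitation handles the textbook cases", {
  # perfectly congruent: one orthogroup spanning all species
  tr <- ape::read.tree(
    text = "((((m_1,(z_1,x_1)),s_1),c_1),p_1);")
  li <- leafTable(tr$tip.label,
                  c("dom", "spic", "mac", "spr", "car", "pah"))
  ogs <- delimitOrthogroups(tr, li, minSupport = NA,
                            referenceSpecies = "dom")
  expect_identical(length(ogs), 1L)
  expect_identical(ogTable(ogs)$n_species, 6L)
  # within-species pair is a local duplication, not a split
  tr2 <- ape::read.tree(text = "((dom_a,dom_b),spr_1);")
  li2 <- leafTable(tr2$tip.label, c("dom", "dom", "spr"))
  ogs2 <- delimitOrthogroups(tr2, li2, minSupport = NA,
                             referenceSpecies = "dom")
  expect_identical(length(ogs2), 1L)
  expect_identical(ogTable(ogs2)$n_species, 2L)
  expect_identical(ogTable(ogs2)$n_members, 3L)
  # cross-species duplication splits the tree
  tr3 <- ape::read.tree(text = "((dom_a,spr_a),(dom_b,spr_b));")
  li3 <- leafTable(tr3$tip.label, c("dom", "spr", "dom", "spr"))
  ogs3 <- delimitOrthogroups(tr3, li3, minSupport = NA,
                             referenceSpecies = "dom")
  expect_identical(length(ogs3), 2L)
})

test_that("delimitation equals the naive reconciliation oracle", {
  species3 <- c("dom", "spr", "car")
  # exhaustive: all rooted binary topologies on 2-4 leaves x all species
  # assignments over 3 species
  for (n in 2:4) {
    labs <- paste0("L", seq_len(n))
    shapes <- enumerateRootedTrees(labs)
    assigns <- expand.grid(rep(list(species3), n),
                           stringsAsFactors = FALSE)
    for (shape in shapes) {
      tr <- ape::read.tree(text = paste0(shape, ";"))
      tr$edge.length <- rep(1, nrow(tr$edge))
      for (r in seq_len(nrow(assigns))) {
        sp <- unlist(assigns[r, ])
        names(sp) <- labs
        li <- leafTable(tr$tip.label, unname(sp[tr$tip.label]))
        got <- canonicalPartition(unname(ogMembers(
          delimitOrthogroups(tr, li, minSupport = NA,
                             referenceSpecies = "dom"))))
        want <- canonicalPartition(oracleDelimit(tr, sp))
        expect_identical(got, want)
      }
    }
  }
  # random larger trees, 5-8 leaves
  set.seed(77)
  for (i in 1:300) {
    n <- sample(5:8, 1)
    labs <- paste0("L", seq_len(n))
    tr <- randomRootedTree(labs)
    sp <- sample(species3, n, replace = TRUE)
    names(sp) <- labs
    li <- leafTable(tr$tip.label, unname(sp[tr$tip.label]))
    got <- canonicalPartition(unname(ogMembers(
      delimitOrthogroups(tr, li, minSupport = NA,
                         referenceSpecies = "dom"))))
    expect_identical(got, canonicalPartition(oracleDelimit(tr, sp)))
  }
})

test_that("duplication-free simulated families are recovered exactly", {
  tr <- musSpeciesTree()
  for (s in 1:200) {
    p <- SimParams(seed = 300L + s, nRootGenes = 3L, dupRate = 0,
                   lossRate = 1)
    truth <- simulateFamily(tr, p)
    gt <- geneTree(truth)
    if (is.null(gt)) next
    og <- trueOrthogroups(truth)
    li <- leafTable(gt$tip.label,
                    vapply(strsplit(gt$tip.label, "|", fixed = TRUE),
                           `[[`, character(1), 1))
    got <- delimitOrthogroups(gt, li, minSupport = NA)
    # exact partition recovery (Rand index 1): members grouped exactly by
    # true orthogroup label
    want <- canonicalPartition(unname(split(
      gt$tip.label,
      unname(og[vapply(strsplit(gt$tip.label, "|", fixed = TRUE),
                       `[[`, character(1), 2)]))))
    expect_identical(canonicalPartition(unname(ogMembers(got))), want)
  }
})

test_that("orthogroup naming follows the annotation grammar", {
  # two reference genes -> combination-ID
  tr <- ape::read.tree(text = "((refA,refB),(spr_1,car_1));")
  li <- data.frame(label = tr$tip.label,
                   species = c("dom", "dom", "spr", "car"),
                   refGene = c("Vmn1r30", "Vmn1r25", NA, NA),
                   stringsAsFactors = FALSE)
  ogs <- delimitOrthogroups(tr, li, minSupport = NA,
                            referenceSpecies = "dom")
  ogs <- nameOrthogroups(ogs, tr, li)
  expect_true("Vmn1r25/30" %in% ogTable(ogs)$name)
  # basal group with <= 3 enclosing reference genes -> combination-ID
  tr2 <- ape::read.tree(
    text = "(spr_x,((ref90,spr_90),(ref168,ref177)));")
  li2 <- data.frame(label = tr2$tip.label,
                    species = c("spr", "dom", "spr", "dom", "dom"),
                    refGene = c(NA, "Vmn1r90", NA, "Vmn1r168",
                                "Vmn1r177"),
                    stringsAsFactors = FALSE)
  ogs2 <- delimitOrthogroups(tr2, li2, minSupport = NA,
                             referenceSpecies = "dom")
  ogs2 <- nameOrthogroups(ogs2, tr2, li2)
  expect_true("Vmn1r90/168/177" %in% ogTable(ogs2)$name)
  # more than three -> basal + lowest id (spr_b makes the inner node a
  # duplication so spr_x is cut off as a basal singleton)
  tr3 <- ape::read.tree(
    text = "(spr_x,((ref90,spr_b),(ref12,(ref168,ref177))));")
  li3 <- data.frame(label = tr3$tip.label,
                    species = c("spr", "dom", "spr", "dom", "dom",
                                "dom"),
                    refGene = c(NA, "Vmn1r90", NA, "Vmn1r12",
                                "Vmn1r168", "Vmn1r177"),
                    stringsAsFactors = FALSE)
  ogs3 <- delimitOrthogroups(tr3, li3, minSupport = NA,
                             referenceSpecies = "dom")
  ogs3 <- nameOrthogroups(ogs3, tr3, li3)
  expect_true("basalVmn1r12" %in% ogTable(ogs3)$name)
  # combination naming is invariant under leaf permutation
  tr4 <- ape::read.tree(text = "((refB,refA),(car_1,spr_1));")
  li4 <- li[match(c("refB", "refA", "car_1", "spr_1"), li$label), ]
  ogs4 <- nameOrthogroups(
    delimitOrthogroups(tr4, li4, minSupport = NA,
                       referenceSpecies = "dom"), tr4, li4)
  expect_true("Vmn1r25/30" %in% ogTable(ogs4)$name)
})

test_that("orthology categories partition and rank correctly", {
  mk <- function(spset) {
    tab <- data.frame(name = "x", n_members = length(spset),
                      n_species = length(spset),
                      species_set = paste(sort(spset), collapse = ","),
                      reference_genes = "", category = NA_character_,
                      clade = NA_character_, stringsAsFactors = FALSE)
    ogs <- new("OrthogroupSet", table = tab,
               members = list(x = paste0(spset, "_t")))
    ogTable(categorizeOrthogroups(ogs))$category
  }
  expect_identical(mk("domesticus"), "reference_only")
  expect_identical(mk("spicilegus"), "non_orthologous")
  # detected in only the reference and one close relative -> low
  expect_identical(mk(c("domesticus", "spicilegus")), "low_orthology")
  # four derived species without the two basal ones -> high
  expect_identical(mk(c("domesticus", "spicilegus", "macedonicus",
                        "spretus")), "high_orthology")
  expect_identical(mk(c("domesticus", "spicilegus", "macedonicus",
                        "spretus", "caroli", "pahari")),
                   "high_orthology")
  # adding a species never lowers the category rank
  rank <- c(reference_only = 1, non_orthologous = 1, low_orthology = 2,
            high_orthology = 3)
  all6 <- c("domesticus", "spicilegus", "macedonicus", "spretus",
            "caroli", "pahari")
  set.seed(4)
  for (i in 1:30) {
    spset <- sample(all6, sample(5, 1))
    extra <- sample(setdiff(all6, spset), 1)
    expect_gte(rank[mk(c(spset, extra))], rank[mk(spset)])
  }
})

test_that("low-support edges collapse before reconciliation", {
  # weak edge separating dom_a from (dom_b, spr): with support 30 the
  # polytomy is resolved conservatively and no duplication is inferred
  tr <- ape::read.tree(text = "((dom_a,(dom_b,spr_1)30)90,car_1);")
  tr$edge.length <- rep(1, nrow(tr$edge))
  li <- leafTable(tr$tip.label, c("dom", "dom", "spr", "car"))
  strict <- delimitOrthogroups(tr, li, minSupport = NA,
                               referenceSpecies = "dom")
  relaxed <- delimitOrthogroups(tr, li, minSupport = 50,
                                referenceSpecies = "dom")
  expect_gt(length(strict), length(relaxed))
  expect_identical(length(relaxed), 1L)
})
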