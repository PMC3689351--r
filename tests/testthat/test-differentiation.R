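twoUnitTable <- function(labelsA, labelsB) {
  # build an alignment realizing the given per-individual haplotype labels
  seqFor <- setNames(
    c("AAA", "TTT", "GGG", "CCC", "A-A"),
    c("h1", "h2", "h3", "h4", "h5")
  )
  labs <- c(labelsA, labelsB)
  seqs <- unname(seqFor[labs])
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  aln <- toyAlignment(seqs, locality = rep(c("AA", "BB"), c(length(labelsA), length(labelsB))))
  collapseHaplotypes(aln)
}

test_that("fixed disjoint units give F_ST 1; identical frequencies give <= 0", {
  tab <- twoUnitTable(rep("h1", 5), rep("h2", 5))
  expect_equal(pairwiseFst(tab, "AA", "BB"), 1)
  tab2 <- twoUnitTable(c("h1", "h1", "h2", "h2"), c("h1", "h1", "h2", "h2"))
  expect_lte(pairwiseFst(tab2, "AA", "BB"), 0)
  # identical single-haplotype pools: d_b = 0 -> 0 by convention
  tab3 <- twoUnitTable(rep("h1", 3), rep("h1", 3))
  expect_equal(pairwiseFst(tab3, "AA", "BB"), 0)
})

test_that("the worked A={h1,h1,h2}, B={h2,h2,h2} value is exactly 0.5", {
  tab <- twoUnitTable(c("h1", "h1", "h2"), c("h2", "h2", "h2"))
  expect_equal(pairwiseFst(tab, "AA", "BB"), 0.5)
})

test_that("pairwiseFst equals the exhaustive pair-enumeration oracle", {
  set.seed(77)
  for (rep_ in 1:40) {
    nA <- sample(2:6, 1)
    nB <- sample(2:6, 1)
    if (nA + nB > 12) next
    labelsA <- sample(paste0("h", 1:4), nA, replace = TRUE)
    labelsB <- sample(paste0("h", 1:4), nB, replace = TRUE)
    tab <- twoUnitTable(labelsA, labelsB)
    expect_equal(
      pairwiseFst(tab, "AA", "BB"),
      oracleFst(labelsA, labelsB),
      tolerance = 1e-12
    )
  }
})

test_that("units with fewer than two individuals are rejected", {
  tab <- twoUnitTable(c("h1"), c("h2", "h2"))
  expect_error(pairwiseFst(tab, "AA", "BB"), "fewer than 2")
  expect_error(
    fstPermutationTest(tab, "AA", "BB", nPermutations = 10, seed = 1),
    "fewer than 2"
  )
})

test_that("permutation p-values: minimum attainable for disjoint units, 1 under identity", {
  tab <- twoUnitTable(rep("h1", 10), rep("h2", 10))
  r <- fstPermutationTest(tab, "AA", "BB", nPermutations = 999, seed = 42)
  expect_equal(r@fst, 1)
  expect_equal(r@pValue, 1 / 1000)
  tab2 <- twoUnitTable(rep("h1", 5), rep("h1", 5))
  r2 <- fstPermutationTest(tab2, "AA", "BB", nPermutations = 99, seed = 1)
  expect_equal(r2@fst, 0)
  expect_equal(r2@pValue, 1)
  expect_error(
    fstPermutationTest(tab, "AA", "BB", nPermutations = 0, seed = 1),
    "nPermutations"
  )
})

test_that("permutation p is reproducible by seed and invariant to label swap", {
  set.seed(5)
  labelsA <- sample(paste0("h", 1:3), 8, replace = TRUE)
  labelsB <- sample(paste0("h", 1:3), 6, replace = TRUE)
  tab <- twoUnitTable(labelsA, labelsB)
  r1 <- fstPermutationTest(tab, "AA", "BB", nPermutations = 499, seed = 11)
  r2 <- fstPermutationTest(tab, "AA", "BB", nPermutations = 499, seed = 11)
  r3 <- fstPermutationTest(tab, "BB", "AA", nPermutations = 499, seed = 11)
  expect_equal(r1@pValue, r2@pValue)
  expect_equal(r1@fst, r3@fst)
  # same partition statistics; swap symmetry of the observed statistic
  expect_equal(abs(r1@pValue - r3@pValue) < 0.05, TRUE)
})

test_that("fst matrix covers all pairs symmetrically with block structure", {
  aln <- toyAlignment(
    c(
      a1 = "AAA", a2 = "AAA", a3 = "TTT",
      b1 = "AAA", b2 = "AAA", b3 = "TTT",
      c1 = "GGG", c2 = "GGG", c3 = "GGG"
    ),
    locality = c("AA", "AA", "AA", "BB", "BB", "BB", "CC", "CC", "CC")
  )
  tab <- collapseHaplotypes(aln)
  fm <- fstMatrix(tab, nPermutations = 199, seed = 2)
  fst <- fstValues(fm)
  expect_identical(fst, t(fst))
  expect_equal(unname(diag(fst)), c(0, 0, 0))
  expect_lte(fst["AA", "BB"], 0) # identical pools
  # AA/BB are polymorphic, CC fixed and disjoint from both:
  # d_w = (2/3 + 0)/2 = 1/3, d_b = 1 -> F_ST = 2/3
  expect_equal(unname(fst["AA", "CC"]), 2 / 3)
  expect_equal(unname(fst["BB", "CC"]), 2 / 3)
  # deterministic given master seed
  fm2 <- fstMatrix(tab, nPermutations = 199, seed = 2)
  expect_identical(fstPValues(fm), fstPValues(fm2))
})

test_that("single unit and undersized pairs are handled", {
  aln <- toyAlignment(c(a1 = "AAA", a2 = "TTT"), locality = c("AA", "AA"))
  tab <- collapseHaplotypes(aln)
  fm <- fstMatrix(tab, nPermutations = 9, seed = 1)
  expect_equal(dim(fstValues(fm)), c(1L, 1L))
  expect_equal(fstValues(fm)[1, 1], 0)
  aln2 <- toyAlignment(c(a1 = "AAA", a2 = "TTT", b1 = "AAA"),
    locality = c("AA", "AA", "BB")
  )
  tab2 <- collapseHaplotypes(aln2)
  expect_warning(fm2 <- fstMatrix(tab2, nPermutations = 9, seed = 1), "skipped")
  expect_true(is.na(fstValues(fm2)["AA", "BB"]))
})

test_that("sequence-mismatch distance variant behaves sensibly", {
  tab <- twoUnitTable(c("h1", "h1", "h2"), c("h2", "h2", "h2"))
  fid <- pairwiseFst(tab, "AA", "BB", distance = "identity")
  fsq <- pairwiseFst(tab, "AA", "BB", distance = "sequence")
  # identity and 0/1-scaled mismatch agree here because h1/h2 differ at all
  # three variable columns (distance constant across unequal pairs)
  expect_equal(fid, fsq)
})
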