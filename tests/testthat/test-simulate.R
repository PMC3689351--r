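smallCfg <- function(seed = 1, ...) {
  simConfig(
    seed = seed, nLocalities = 8, countrySizes = c(4L, 4L),
    samplesPerLocality = 14, subcladesPerClade = c(2L, 2L),
    haplotypesPerLocality = 5, ...
  )
}

test_that("identical config and seed give byte-identical outputs", {
  cfg <- smallCfg(seed = 42)
  s1 <- simulateMtdna(cfg)
  s2 <- simulateMtdna(cfg)
  expect_identical(
    as.character(s1$alignment@seqs),
    as.character(s2$alignment@seqs)
  )
  expect_identical(s1$truth$subclade, s2$truth$subclade)
  r1 <- simulateNuclearAssignments(cfg, s1$truth)
  r2 <- simulateNuclearAssignments(cfg, s2$truth)
  expect_identical(r1, r2)
  # a different seed changes the draw
  s3 <- simulateMtdna(cfg, seed = 43)
  expect_false(identical(
    as.character(s1$alignment@seqs),
    as.character(s3$alignment@seqs)
  ))
})

test_that("config invariants are enforced", {
  expect_error(
    simConfig(samplesPerLocality = 5, haplotypesPerLocality = 5),
    "samplesPerLocality"
  )
  expect_error(simConfig(privateFraction = 1.2), "privateFraction")
  expect_error(
    simConfig(
      nLocalities = 8, countrySizes = c(4L, 4L),
      subcladesPerClade = c(5L, 3L), privateFraction = 0.5
    ),
    "2 localities"
  )
  expect_error(
    simConfig(
      L = 100L, nLocalities = 8, countrySizes = c(4L, 4L),
      subcladesPerClade = c(2L, 2L)
    ),
    "mutation budget"
  )
})

test_that("the planted key is recovered from labeled training data", {
  sim <- simulateMtdna(smallCfg(seed = 2))
  tab <- collapseHaplotypes(sim$alignment)
  labs <- sim$truth$haplotypes$subclade[
    vapply(
      haplotypeMembers(tab),
      function(m) unname(sim$truth$haplotype[m[1]]), character(1)
    )
  ]
  names(labs) <- names(haplotypeSequences(tab))
  key <- deriveDiagnosticKey(tab, labs, sim$truth$hierarchy)
  s <- key@sites
  nFixed <- sim$truth$key@sites$column
  # every planted diagnostic column is recovered at the right level
  planted <- sim$truth$key@sites
  for (i in seq_len(nrow(planted))) {
    hit <- s$column == planted$column[i] & s$level == planted$level[i] & s$fixed
    expect_true(any(hit))
  }
  # at least nFixedSitesPerSplit fixed sites per subclade split
  for (sub in unlist(sim$truth$hierarchy)) {
    nSub <- sum(vapply(seq_len(nrow(s)), function(i) {
      s$fixed[i] && s$level[i] == "subclade" && sub %in% key@stateMaps[[i]]
    }, logical(1)))
    expect_gte(nSub, 2L)
  }
})

test_that("private fraction limits drive sharing: p=1 disjoint, p=0 dense", {
  sim1 <- simulateMtdna(smallCfg(seed = 4, privateFraction = 1))
  tab1 <- collapseHaplotypes(sim1$alignment)
  sp <- haplotypeSpecificity(tab1, "locality")
  expect_equal(unname(sp$hapFractionBySpread["1"]), 1)
  sh1 <- sharingMatrix(tab1)
  expect_true(all(sh1[upper.tri(sh1)] == 0))

  sim0 <- simulateMtdna(smallCfg(seed = 4, privateFraction = 0))
  tab0 <- collapseHaplotypes(sim0$alignment)
  sh0 <- sharingMatrix(tab0)
  expect_gt(sum(sh0[upper.tri(sh0)] > 0), 0)
  expect_equal(
    unname(haplotypeSpecificity(tab0, "locality")$hapFractionBySpread["1"]) %||% 0,
    0
  )
})

test_that("nuclear mis-assignment rate is honored at the extremes and in law", {
  cfg0 <- smallCfg(seed = 6, nuclearMisassignmentRate = 0)
  sim <- simulateMtdna(cfg0)
  rec0 <- simulateNuclearAssignments(cfg0, sim$truth)
  expect_true(all(rec0$true_locality == rec0$assigned_locality))

  cfg1 <- smallCfg(seed = 6, nuclearMisassignmentRate = 1)
  rec1 <- simulateNuclearAssignments(cfg1, sim$truth)
  expect_true(all(rec1$true_locality != rec1$assigned_locality))

  # rate 0.45, n = 112: count within the binomial 99.9% interval
  cfg45 <- smallCfg(seed = 6, nuclearMisassignmentRate = 0.45)
  rec45 <- simulateNuclearAssignments(cfg45, sim$truth)
  mis <- sum(rec45$true_locality != rec45$assigned_locality)
  n <- nrow(rec45)
  bounds <- qbinom(c(0.0005, 0.9995), n, 0.45)
  expect_gte(mis, bounds[1])
  expect_lte(mis, bounds[2])
  # mis-assignment is independent of subclade: assigned localities include
  # other subclade regions
  home <- sim$truth$homeSubclade
  wrong <- rec1$assigned_locality
  expect_gt(length(unique(home[wrong])), 1L)
})

test_that("species groups follow the locality's clade region", {
  sim <- simulateMtdna(smallCfg(seed = 8))
  meta <- as.data.frame(sampleData(sim$alignment))
  cladeOf <- setNames(
    rep(names(sim$truth$hierarchy), lengths(sim$truth$hierarchy)),
    unlist(sim$truth$hierarchy)
  )
  expected <- ifelse(cladeOf[sim$truth$homeSubclade[meta$locality]] == "F",
    "forest", "savanna"
  )
  expect_identical(meta$species, unname(expected))
})

test_that("missing rate masks bases to N approximately at rate", {
  cfg <- smallCfg(seed = 10, missingRate = 0.02)
  sim <- simulateMtdna(cfg)
  m <- mtprov:::.seqMatrix(sim$alignment)
  frac <- mean(m == "N")
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.03)
})

test_that("YAML/JSON configs round-trip into simConfig", {
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(
      seed = 3, nLocalities = 8, countrySizes = c(4L, 4L),
      samplesPerLocality = 14, subcladesPerClade = c(2L, 2L)
    ),
    js,
    auto_unbox = TRUE
  )
  cfg <- readSimConfig(js)
  expect_s3_class(cfg, "SimConfig")
  expect_equal(cfg$nLocalities, 8L)
})
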