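# two-clade toy with one subclade pair per clade; columns 1-2 separate the
# clades, column 3 separates f1/f2, column 4 separates s1/s2
toyKeySetup <- function() {
  seqs <- c(
    h1 = "ACAAT", h2 = "ACCAT", # clade F: f1 (A at col3), f2 (C at col3)
    h3 = "GTAAT", h4 = "GTAGT" # clade S: s1 (A at col4), s2 (G at col4)
  )
  aln <- toyAlignment(seqs, locality = c("AA", "AA", "BB", "BB"))
  tab <- collapseHaplotypes(aln)
  # hap ids are count/lexicographic ordered; label by sequence content
  bySeq <- setNames(names(haplotypeSequences(tab)), unname(haplotypeSequences(tab)))
  labels <- setNames(
    c("western", "west-central", "savanna-wide", "southeast-savanna"),
    bySeq[c("ACAAT", "ACCAT", "GTAAT", "GTAGT")]
  )
  hierarchy <- list(
    F = c("western", "west-central"),
    S = c("savanna-wide", "southeast-savanna")
  )
  list(tab = tab, labels = labels, hierarchy = hierarchy)
}

test_that("derived key finds clade partitions and subclade-fixed states", {
  ts <- toyKeySetup()
  key <- deriveDiagnosticKey(ts$tab, ts$labels, ts$hierarchy)
  s <- key@sites
  cladeCols <- s$column[s$level == "clade" & s$fixed]
  expect_setequal(cladeCols, c(1L, 2L))
  expect_true(all(c(3L, 4L) %in% s$column[s$level == "subclade" & s$fixed]))
  # column 5 is constant, never a site
  expect_false(5L %in% s$column)
})

test_that("fixed candidates with one exception degrade to voting sites", {
  seqs <- c(
    h1 = "AAC", h2 = "AAG", h3 = "ATC", # f1, f1, f2 : col2 A/A/T
    h4 = "GTA", h5 = "GCA" # s1, s2
  )
  aln <- toyAlignment(seqs)
  tab <- collapseHaplotypes(aln)
  bySeq <- setNames(names(haplotypeSequences(tab)), unname(haplotypeSequences(tab)))
  labels <- setNames(
    c("western", "western", "west-central", "savanna-wide", "southeast-savanna"),
    bySeq[c("AAC", "AAG", "ATC", "GTA", "GCA")]
  )
  hierarchy <- list(
    F = c("western", "west-central"),
    S = c("savanna-wide", "southeast-savanna")
  )
  key <- deriveDiagnosticKey(tab, labels, hierarchy)
  s <- key@sites
  # within F, column 2: T confined to west-central but A also occurs in
  # west-central? no: A carried by both western haplotypes and T by the one
  # west-central haplotype -> T is fixed for west-central
  f2 <- s[s$level == "subclade" & s$parent == "F" & s$column == 2L, ]
  expect_true(nrow(f2) == 1L && f2$fixed)
  # within F, column 3: C occurs in western AND west-central, G only in
  # western but western also carries C -> voting site, not fixed
  f3 <- s[s$level == "subclade" & s$parent == "F" & s$column == 3L, ]
  expect_true(nrow(f3) == 1L && !f3$fixed)
})

test_that("derivation requires every subclade to have training haplotypes", {
  ts <- toyKeySetup()
  hierarchy <- ts$hierarchy
  hierarchy$F <- c(hierarchy$F, "north-central")
  expect_error(
    deriveDiagnosticKey(ts$tab, ts$labels, hierarchy),
    "north-central"
  )
})

test_that("classification walks clade then subclade and handles missingness", {
  ts <- toyKeySetup()
  key <- deriveDiagnosticKey(ts$tab, ts$labels, ts$hierarchy)
  # full sequence matches its training label
  res <- classifySequence("ACAAT", key)
  expect_identical(res$clade, "F")
  expect_identical(res$subclade, "western")
  # N at every clade site -> unassigned, stop
  res2 <- classifySequence("NNAAT", key)
  expect_identical(res2$clade, "unassigned")
  expect_identical(res2$subclade, "unassigned")
  # partial sequence with one usable site per level still assigned
  res3 <- classifySequence("ANANN", key)
  expect_identical(res3$clade, "F")
  expect_identical(res3$subclade, "western")
  expect_gt(res3$nSitesMissing, 0L)
})

test_that("training haplotypes reclassify perfectly with zero conflicts", {
  ts <- toyKeySetup()
  key <- deriveDiagnosticKey(ts$tab, ts$labels, ts$hierarchy)
  for (h in names(ts$labels)) {
    res <- classifySequence(unname(haplotypeSequences(ts$tab)[h]), key)
    expect_identical(res$subclade, unname(ts$labels[h]))
  }
})

test_that("hierarchy consistency: subclade labels imply the matching clade", {
  sim <- simulateMtdna(simConfig(
    seed = 5, nLocalities = 8, countrySizes = c(4L, 4L),
    samplesPerLocality = 14, missingRate = 0.05,
    subcladesPerClade = c(2L, 2L)
  ))
  cl <- classifyDataset(sim$alignment, sim$truth$key)
  a <- cl$assignments
  subs <- a$subclade %in% unlist(sim$truth$hierarchy)
  cladeOf <- setNames(
    rep(names(sim$truth$hierarchy), lengths(sim$truth$hierarchy)),
    unlist(sim$truth$hierarchy)
  )
  expect_true(all(a$clade[subs] == cladeOf[a$subclade[subs]]))
})

test_that("masking a diagnostic column degrades but never flips labels", {
  sim <- simulateMtdna(simConfig(
    seed = 3, nLocalities = 8, countrySizes = c(4L, 4L),
    samplesPerLocality = 14, subcladesPerClade = c(2L, 2L)
  ))
  aln <- sim$alignment
  key <- sim$truth$key
  truth <- sim$truth$subclade
  # mask each diagnostic column in turn across all samples
  m <- mtprov:::.seqMatrix(aln)
  for (col in unique(key@sites$column)[1:6]) {
    m2 <- m
    m2[, col] <- "N"
    seqs <- apply(m2, 1, paste, collapse = "")
    aln2 <- MtAlignment(seqs, as.data.frame(sampleData(aln)), frame = aln@frame)
    cl <- classifyDataset(aln2, key)
    lab <- cl$assignments$subclade
    ok <- lab == unname(truth[cl$assignments$sample_id]) | lab == "unassigned"
    expect_true(all(ok))
    expect_false(any(lab == "conflict"))
  }
})

test_that("forest-species samples in S clade are flagged, and empty input works", {
  ts <- toyKeySetup()
  key <- deriveDiagnosticKey(ts$tab, ts$labels, ts$hierarchy)
  aln <- toyAlignment(c(x1 = "GTAAT"), species = "forest")
  cl <- classifyDataset(aln, key)
  expect_identical(cl$speciesCladeFlags, "x1")
  empty <- classifyDataset(aln[0], key)
  expect_equal(nrow(empty$assignments), 0L)
})

test_that("keys serialize losslessly to JSON and usably to TSV", {
  ts <- toyKeySetup()
  key <- deriveDiagnosticKey(ts$tab, ts$labels, ts$hierarchy)
  js <- tempfile(fileext = ".json")
  writeDiagnosticKey(key, js)
  back <- readDiagnosticKey(js)
  expect_equal(back@sites$column, key@sites$column)
  expect_equal(back@sites$fixed, key@sites$fixed)
  expect_equal(back@stateMaps, key@stateMaps)
  expect_equal(back@hierarchy, key@hierarchy)
  tsv <- tempfile(fileext = ".tsv")
  writeDiagnosticKey(key, tsv)
  back2 <- readDiagnosticKey(tsv)
  res <- classifySequence("ACAAT", back2)
  expect_identical(res$subclade, "western")
})
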