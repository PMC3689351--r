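test_that("two haplotypes connect by a single edge of their distance", {
  aln <- toyAlignment(c(a = "AAAA", b = "ATTA"), locality = c("AA", "BB"))
  net <- buildMJNetwork(collapseHaplotypes(aln))
  g <- networkGraph(net)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 2)
  expect_equal(networkCost(net), 2)
})

test_that("a star triple is resolved by one central median vector", {
  aln <- toyAlignment(c(x = "TAA", y = "ATA", z = "AAT"))
  net <- buildMJNetwork(collapseHaplotypes(aln))
  g <- networkGraph(net)
  kind <- igraph::V(g)$kind
  expect_equal(sum(kind == "median"), 1L)
  med <- igraph::V(g)$sequence[kind == "median"]
  expect_identical(med, "AAA")
  expect_equal(networkCost(net), 3) # beats any pairwise chain (cost 4)
  expect_equal(sort(igraph::E(g)$weight), c(1, 1, 1))
  expect_equal(igraph::V(g)$frequency[kind == "median"], 0)
})

test_that("two tight clusters join only through their closest pair", {
  aln <- toyAlignment(c(
    a1 = "AAAAAA", a2 = "AAAAAT", # cluster 1
    b1 = "TTTTAA", b2 = "TTTTAT" # cluster 2
  ))
  net <- buildMJNetwork(collapseHaplotypes(aln), epsilon = 0L)
  g <- networkGraph(net)
  df <- igraph::as_data_frame(g, what = "edges")
  seqOf <- setNames(igraph::V(g)$sequence, igraph::V(g)$name)
  cluster <- function(s) substr(s, 1, 1)
  inter <- df[cluster(seqOf[df$from]) != cluster(seqOf[df$to]), ]
  expect_equal(nrow(inter), 2L) # ties: a1-b1 and a2-b2 both minimal (4)
  expect_true(all(inter$weight == 4))
  expect_equal(networkCost(net), oracleSteinerCost(mtprov:::.seqMatrix(
    c("AAAAAA", "AAAAAT", "TTTTAA", "TTTTAT")
  )))
})

test_that("haplotypes with N at variable sites are rejected with guidance", {
  tab <- collapseHaplotypes(toyAlignment(c(a = "AAA", b = "TTT")))
  tab@sequences[1] <- "ANA"
  expect_error(buildMJNetwork(tab), "N at variable sites")
})

test_that("every observed haplotype appears once and the network is connected", {
  set.seed(31)
  for (rep_ in 1:10) {
    ns <- sample(3:6, 1)
    k <- sample(3:min(5, ns + 1), 1)
    tm <- randomTreelike(k, ns)
    seqs <- apply(tm, 1, paste, collapse = "")
    names(seqs) <- sprintf("s%d", seq_len(k))
    tab <- collapseHaplotypes(toyAlignment(seqs))
    net <- buildMJNetwork(tab)
    g <- networkGraph(net)
    obs <- igraph::V(g)$name[igraph::V(g)$kind == "observed"]
    expect_setequal(obs, names(haplotypeSequences(tab)))
    expect_true(igraph::is_connected(g))
    expect_true(all(igraph::E(g)$weight >= 1))
    expect_false(igraph::any_multiple(g))
  }
})

test_that("medians never raise the cost above the observed-only spanning tree", {
  set.seed(53)
  for (rep_ in 1:20) {
    k <- sample(3:5, 1)
    L <- sample(3:6, 1)
    tm <- randomBinaryHaplotypes(k, L)
    seqs <- apply(tm, 1, paste, collapse = "")
    names(seqs) <- sprintf("s%d", seq_len(k))
    net <- buildMJNetwork(collapseHaplotypes(toyAlignment(seqs)))
    mst <- mtprov:::.mstCost(mtprov:::.rowHamming(tm))
    steiner <- oracleSteinerCost(tm)
    expect_lte(networkCost(net), mst)
    expect_gte(networkCost(net), steiner)
  }
})

test_that("subclade labels group contiguously on structured data", {
  sim <- simulateMtdna(simConfig(
    seed = 21, nLocalities = 8, countrySizes = c(4L, 4L),
    samplesPerLocality = 14, subcladesPerClade = c(2L, 2L),
    haplotypesPerLocality = 4
  ))
  tab <- collapseHaplotypes(sim$alignment)
  net <- buildMJNetwork(tab)
  labs <- sim$truth$haplotypes$subclade[
    vapply(
      haplotypeMembers(tab),
      function(m) unname(sim$truth$haplotype[m[1]]), character(1)
    )
  ]
  names(labs) <- names(haplotypeSequences(tab))
  res <- subcladeGroupingCheck(net, labs)
  expect_true(res$ok)
  expect_length(res$offenders, 0L)
})

test_that("interleaved labels on a path are reported as offenders", {
  # path: AAAA - AAAT - AATT - ATTT with labels X,Y,X,Y
  aln <- toyAlignment(c(a = "AAAA", b = "AAAT", c = "AATT", d = "ATTT"))
  tab <- collapseHaplotypes(aln)
  net <- buildMJNetwork(tab)
  bySeq <- setNames(names(haplotypeSequences(tab)), unname(haplotypeSequences(tab)))
  labs <- setNames(
    c("X", "Y", "X", "Y"),
    bySeq[c("AAAA", "AAAT", "AATT", "ATTT")]
  )
  res <- subcladeGroupingCheck(net, labs)
  expect_false(res$ok)
  expect_gt(length(res$offenders), 0L)
  # single label is trivially grouped
  labs1 <- setNames(rep("X", 4), names(haplotypeSequences(tab)))
  expect_true(subcladeGroupingCheck(net, labs1)$ok)
  expect_error(
    subcladeGroupingCheck(net, labs[-1]),
    "unlabeled"
  )
})

test_that("network exports to GML and DOT", {
  net <- buildMJNetwork(collapseHaplotypes(toyAlignment(
    c(x = "TAA", y = "ATA", z = "AAT")
  )))
  gml <- tempfile(fileext = ".gml")
  dot <- tempfile(fileext = ".dot")
  writeNetwork(net, gml)
  writeNetwork(net, dot)
  expect_true(file.size(gml) > 0)
  expect_true(any(grepl("median", readLines(gml))))
  expect_true(file.size(dot) > 0)
})
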