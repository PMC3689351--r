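# Independent brute-force oracles used to validate the implementation on
# small instances. These deliberately share no code with the package.

# haplotype group sizes by exhaustive pairwise sequence comparison
oracleHaplotypeCounts <- function(seqs) {
  n <- length(seqs)
  assigned <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    g <- g + 1L
    assigned[i] <- g
    if (i < n) {
      for (j in seq.int(i + 1L, n)) {
        if (is.na(assigned[j]) && identical(seqs[[j]], seqs[[i]])) assigned[j] <- g
      }
    }
  }
  sort(as.integer(table(assigned)), decreasing = TRUE)
}

# F_ST by explicit enumeration of every within- and cross-population pair,
# using haplotype-identity distance on per-individual haplotype labels
oracleFst <- function(labelsA, labelsB) {
  meanPairs <- function(x) {
    n <- length(x)
    tot <- 0
    cnt <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        tot <- tot + (x[i] != x[j])
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  db <- 0
  for (a in labelsA) {
    for (b in labelsB) db <- db + (a != b)
  }
  db <- db / (length(labelsA) * length(labelsB))
  if (db == 0) {
    return(0)
  }
  (db - (meanPairs(labelsA) + meanPairs(labelsB)) / 2) / db
}

# minimum Steiner-tree cost connecting terminal sequences in the product
# space of per-column observed states, via Dreyfus-Wagner dynamic
# programming on the full candidate vertex set
oracleSteinerCost <- function(termMat) {
  k <- nrow(termMat)
  if (k < 2) {
    return(0)
  }
  stateSets <- lapply(seq_len(ncol(termMat)), function(j) unique(termMat[, j]))
  V <- as.matrix(expand.grid(stateSets, stringsAsFactors = FALSE))
  nV <- nrow(V)
  D <- matrix(0, nV, nV)
  for (j in seq_len(ncol(V))) D <- D + outer(V[, j], V[, j], "!=")
  termIdx <- vapply(seq_len(k), function(i) {
    which(apply(V, 1, function(r) all(r == termMat[i, ])))[1]
  }, integer(1))
  root <- termIdx[k]
  others <- termIdx[-k]
  t <- length(others)
  full <- bitwShiftL(1L, t) - 1L
  dp <- vector("list", full)
  for (i in seq_len(t)) {
    dp[[bitwShiftL(1L, i - 1L)]] <- D[others[i], ]
  }
  masks <- setdiff(seq_len(full), bitwShiftL(1L, seq_len(t) - 1L))
  masks <- masks[order(vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) > 0), numeric(1)))]
  for (m in masks) {
    merged <- rep(Inf, nV)
    sub <- bitwAnd(m, m - 1L)
    while (sub > 0L) {
      rest <- bitwXor(m, sub)
      merged <- pmin(merged, dp[[sub]] + dp[[rest]])
      sub <- bitwAnd(m, sub - 1L)
    }
    dp[[m]] <- apply(merged + D, 2, min)
  }
  dp[[full]][root]
}

# toy MtAlignment builder
toyAlignment <- function(seqs, locality = NULL, country = NULL,
                         species = "savanna") {
  ids <- names(seqs)
  if (is.null(ids)) {
    ids <- sprintf("s%02d", seq_along(seqs))
    names(seqs) <- ids
  }
  if (is.null(locality)) locality <- rep("AA", length(seqs))
  if (is.null(country)) {
    locs <- sort(unique(locality))
    cmap <- setNames(sprintf("C%02d", seq_along(locs)), locs)
    country <- unname(cmap[locality])
  }
  MtAlignment(seqs, data.frame(
    sample_id = ids, locality = locality, country = country,
    species = species, stringsAsFactors = FALSE
  ))
}

# random sequences over a binary state pair per column, all rows distinct
randomBinaryHaplotypes <- function(k, L) {
  repeat {
    m <- matrix(sample(c("A", "T"), k * L, replace = TRUE), nrow = k)
    if (nrow(unique(m)) == k) {
      return(m)
    }
  }
}

# tree-like (infinite-sites) random haplotype matrix: mutations planted on a
# random genealogy, some internal nodes left unobserved, constant columns
# dropped
randomTreelike <- function(k, nSites) {
  repeat {
    pool <- list(rep("A", nSites))
    for (s in seq_len(nSites)) {
      parent <- pool[[sample.int(length(pool), 1)]]
      child <- parent
      child[s] <- "T"
      pool[[length(pool) + 1]] <- child
    }
    pool <- unique(pool)
    if (length(pool) < k) next
    m <- do.call(rbind, pool[sample.int(length(pool), k)])
    keep <- apply(m, 2, function(cl) length(unique(cl)) > 1)
    m <- m[, keep, drop = FALSE]
    if (nrow(unique(m)) == k && ncol(m) >= 1) {
      return(m)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
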