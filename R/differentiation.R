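#' @include AllClasses.R AllGenerics.R utils.R
NULL

# F_ST from per-unit haplotype count vectors.
# Identity distance: d = 0 within a haplotype, 1 between haplotypes, so the
# mean within/between distances reduce to matching-pair counts. An optional
# haplotype-by-haplotype distance matrix D generalizes to sequence-mismatch
# distances.
.fstFromCounts <- function(ca, cb, D = NULL) {
  na <- sum(ca)
  nb <- sum(cb)
  if (is.null(D)) {
    dwA <- if (na < 2) 0 else (choose(na, 2) - sum(choose(ca, 2))) / choose(na, 2)
    dwB <- if (nb < 2) 0 else (choose(nb, 2) - sum(choose(cb, 2))) / choose(nb, 2)
    db <- (na * nb - sum(ca * cb)) / (na * nb)
  } else {
    qa <- as.numeric(crossprod(ca, D %*% ca)) / 2
    qb <- as.numeric(crossprod(cb, D %*% cb)) / 2
    dwA <- if (na < 2) 0 else qa / choose(na, 2)
    dwB <- if (nb < 2) 0 else qb / choose(nb, 2)
    db <- as.numeric(crossprod(ca, D %*% cb)) / (na * nb)
  }
  if (db == 0) {
    return(0)
  }
  (db - (dwA + dwB) / 2) / db
}

.unitCounts <- function(table, unit, level) {
  counts <- haplotypeCounts(table, level = level)
  if (!unit %in% colnames(counts)) {
    stop("unknown unit: ", unit, call. = FALSE)
  }
  counts[, unit]
}

.hapDistances <- function(table) {
  m <- .seqMatrix(table@sequences)[, table@variableSites, drop = FALSE]
  h <- nrow(m)
  D <- matrix(0L, h, h)
  if (h > 1 && ncol(m)) {
    for (j in seq_len(ncol(m))) {
      D <- D + outer(m[, j], m[, j], "!=")
    }
  }
  storage.mode(D) <- "numeric"
  D
}

#' Pairwise haplotype F_ST between two units
#'
#' Computes the haplotype-frequency F_ST between two localities (or
#' countries) using the haplotype-identity distance (0 within a haplotype, 1
#' between haplotypes): with `d_w` the mean distance over unordered
#' within-unit pairs and `d_b` the mean over cross pairs,
#' `F_ST = (d_b - (d_w(A) + d_w(B))/2) / d_b`, and 0 when `d_b = 0`.
#' Negative estimates are reported as computed (finite-sample estimator
#' noise), never clamped. `distance = "sequence"` swaps in the number of
#' differing variable sites as the distance.
#'
#' @param table a [HaplotypeTable-class].
#' @param unitA,unitB unit codes; each must hold at least 2 individuals.
#' @param level `"locality"` or `"country"`.
#' @param distance `"identity"` (haplotype-frequency F_ST, default) or
#'   `"sequence"` (mismatch distances over variable sites).
#' @return The F_ST estimate (numeric scalar, at most 1).
#' @examples
#' # A = {h1,h1,h2}, B = {h2,h2,h2}: F_ST = (2/3 - 1/3) / (2/3) = 0.5
#' @export
pairwiseFst <- function(table, unitA, unitB, level = c("locality", "country"),
                        distance = c("identity", "sequence")) {
  level <- match.arg(level)
  distance <- match.arg(distance)
  ca <- .unitCounts(table, unitA, level)
  cb <- .unitCounts(table, unitB, level)
  if (sum(ca) < 2 || sum(cb) < 2) {
    few <- c(unitA, unitB)[c(sum(ca), sum(cb)) < 2]
    stop("unit(s) with fewer than 2 individuals: ", paste(few, collapse = ", "),
      call. = FALSE
    )
  }
  D <- if (distance == "sequence") .hapDistances(table) else NULL
  .fstFromCounts(ca, cb, D)
}

#' Permutation significance test for pairwise F_ST
#'
#' Pools the two units' individuals, repeatedly re-partitions them at random
#' into groups of the original sizes, and recomputes F_ST. The p-value uses
#' the add-one estimator `p = (1 + #{perm F_ST >= observed}) / (1 + n)`,
#' which is a valid permutation p-value and never exactly zero.
#'
#' @inheritParams pairwiseFst
#' @param nPermutations number of random re-partitions (>= 1); 10 000 is the
#'   conventional choice for locality-pair testing.
#' @param seed integer seed making the test reproducible.
#' @return An [FstResult-class].
#' @export
fstPermutationTest <- function(table, unitA, unitB, nPermutations = 10000L,
                               seed = 1L, level = c("locality", "country"),
                               distance = c("identity", "sequence")) {
  level <- match.arg(level)
  distance <- match.arg(distance)
  nPermutations <- as.integer(nPermutations)
  if (is.na(nPermutations) || nPermutations < 1L) {
    stop("nPermutations must be >= 1", call. = FALSE)
  }
  ca <- .unitCounts(table, unitA, level)
  cb <- .unitCounts(table, unitB, level)
  if (sum(ca) < 2 || sum(cb) < 2) {
    few <- c(unitA, unitB)[c(sum(ca), sum(cb)) < 2]
    stop("unit(s) with fewer than 2 individuals: ", paste(few, collapse = ", "),
      call. = FALSE
    )
  }
  D <- if (distance == "sequence") .hapDistances(table) else NULL
  obs <- .fstFromCounts(ca, cb, D)
  keep <- ca + cb > 0
  ca <- ca[keep]
  cb <- cb[keep]
  if (!is.null(D)) D <- D[keep, keep, drop = FALSE]
  nA <- sum(ca)
  nB <- sum(cb)
  h <- length(ca)
  pool <- rep.int(seq_len(h), ca + cb)
  tot <- ca + cb
  nGe <- 0L
  eps <- 1e-12
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  for (b in seq_len(nPermutations)) {
    idx <- sample.int(nA + nB, nA)
    pa <- tabulate(pool[idx], nbins = h)
    f <- .fstFromCounts(pa, tot - pa, D)
    if (f >= obs - eps) nGe <- nGe + 1L
  }
  new("FstResult",
    unitA = unitA, unitB = unitB, fst = obs,
    pValue = (1 + nGe) / (1 + nPermutations),
    nPermutations = nPermutations, seed = as.integer(seed),
    nA = as.integer(nA), nB = as.integer(nB)
  )
}

#' All-pairs F_ST matrix with permutation p-values
#'
#' Applies [fstPermutationTest()] to every unit pair, with per-pair sub-seeds
#' derived deterministically from the master seed and the ordered pair, so
#' the matrix is reproducible and individual cells can be recomputed in
#' isolation. Pairs failing the minimum-size precondition are recorded as
#' `NA` with a warning.
#'
#' @inheritParams fstPermutationTest
#' @param units optional subset/order of units; defaults to all units in the
#'   table.
#' @return An [FstMatrix-class].
#' @export
fstMatrix <- function(table, units = NULL, nPermutations = 10000L, seed = 1L,
                      level = c("locality", "country"),
                      distance = c("identity", "sequence")) {
  level <- match.arg(level)
  distance <- match.arg(distance)
  counts <- haplotypeCounts(table, level = level)
  if (is.null(units)) units <- colnames(counts)
  k <- length(units)
  fst <- matrix(NA_real_, k, k, dimnames = list(units, units))
  pv <- matrix(NA_real_, k, k, dimnames = list(units, units))
  diag(fst) <- 0
  diag(pv) <- 1
  skipped <- character()
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        ok <- tryCatch(
          {
            r <- fstPermutationTest(table, units[i], units[j],
              nPermutations = nPermutations,
              seed = .subSeed(seed, i, j),
              level = level, distance = distance
            )
            fst[i, j] <- fst[j, i] <- r@fst
            pv[i, j] <- pv[j, i] <- r@pValue
            TRUE
          },
          error = function(e) FALSE
        )
        if (!ok) skipped <- c(skipped, paste0(units[i], "-", units[j]))
      }
    }
  }
  if (length(skipped)) {
    warning(
      "pairs skipped (fewer than 2 individuals): ",
      paste(skipped, collapse = ", ")
    )
  }
  new("FstMatrix",
    units = units, fst = fst, pvalues = pv,
    nPermutations = as.integer(nPermutations), seed = as.integer(seed)
  )
}

#' Accessors for FstMatrix
#'
#' @param x an [FstMatrix-class].
#' @return `fstValues` / `fstPValues`: symmetric numeric matrices.
#' @name FstMatrix-accessors
NULL

#' @rdname FstMatrix-accessors
#' @export
setMethod("fstValues", "FstMatrix", function(x) x@fst)

#' @rdname FstMatrix-accessors
#' @export
setMethod("fstPValues", "FstMatrix", function(x) x@pvalues)

setMethod("show", "FstResult", function(object) {
  cat(sprintf(
    "FstResult %s vs %s: F_ST = %.4f, p = %.4g (%d permutations, n = %d + %d)\n",
    object@unitA, object@unitB, object@fst, object@pValue,
    object@nPermutations, object@nA, object@nB
  ))
})

setMethod("show", "FstMatrix", function(object) {
  k <- length(object@units)
  off <- object@fst[upper.tri(object@fst)]
  cat(sprintf(
    "FstMatrix: %d unit(s), %d permutations per pair (seed %d)\n",
    k, object@nPermutations, object@seed
  ))
  if (length(off)) {
    cat(sprintf(
      "  off-diagonal F_ST: median %.3f, range [%.3f, %.3f]; %d/%d pairs with p < 0.05\n",
      stats::median(off, na.rm = TRUE), min(off, na.rm = TRUE),
      max(off, na.rm = TRUE),
      sum(object@pvalues[upper.tri(object@pvalues)] < 0.05, na.rm = TRUE),
      length(off)
    ))
  }
})
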