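#' @include AllClasses.R AllGenerics.R utils.R
NULL

.TRI_CATEGORIES <- c(
  "nuclear_correct", "mtdna_precludes", "mtdna_distinguishes", "unresolved"
)

#' Read a nuclear assignment record table
#'
#' @param path TSV with header columns `sample_id`, `true_locality`,
#'   `assigned_locality`, `species_group`.
#' @return data.frame of assignment records.
#' @export
readAssignmentRecords <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  req <- c("sample_id", "true_locality", "assigned_locality", "species_group")
  if (!all(req %in% colnames(df))) {
    stop("assignment table needs columns: ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Triangulate nuclear assignments against mtDNA evidence
#'
#' Categorizes every sample by combining its nuclear (e.g. microsatellite)
#' locality assignment with mtDNA haplotype sharing and F_ST significance
#' between the true and assigned localities, in priority order:
#'
#' 1. `nuclear_correct` — the nuclear assignment matched the true locality;
#' 2. `mtdna_precludes` — no mtDNA haplotype is shared between the two
#'    localities, so sequencing mtDNA would have ruled the assignment out;
#' 3. `mtdna_distinguishes` — haplotypes are shared, but the permutation
#'    F_ST between the pair is significant at `alpha`, so haplotype
#'    frequencies can still separate the localities;
#' 4. `unresolved` — none of the above.
#'
#' @param records data.frame with columns `sample_id`, `true_locality`,
#'   `assigned_locality`, `species_group` (values `forest`/`savanna`).
#' @param sharing symmetric shared-haplotype count matrix from
#'   [sharingMatrix()], covering every locality in `records`.
#' @param fst an [FstMatrix-class] covering the same localities.
#' @param alpha significance level for the permutation p-values (raw, no
#'   multiple-testing correction; Bonferroni can be applied by passing
#'   `alpha / nPairs`).
#' @return A [TriangulationReport-class].
#' @export
triangulate <- function(records, sharing, fst, alpha = 0.05) {
  stopifnot(is.data.frame(records), is(fst, "FstMatrix"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  locs <- unique(c(records$true_locality, records$assigned_locality))
  missShare <- setdiff(locs, rownames(sharing))
  missFst <- setdiff(locs, fst@units)
  if (length(missShare) || length(missFst)) {
    stop("locality(ies) absent from sharing/fst matrices: ",
      paste(unique(c(missShare, missFst)), collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(records)
  category <- character(n)
  shared <- integer(n)
  fstv <- pv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- records$true_locality[i]
    b <- records$assigned_locality[i]
    if (a == b) {
      category[i] <- "nuclear_correct"
      shared[i] <- sharing[a, a]
      next
    }
    shared[i] <- sharing[a, b]
    fstv[i] <- fst@fst[a, b]
    pv[i] <- fst@pvalues[a, b]
    if (is.na(shared[i])) {
      stop("sharing matrix has NA for pair ", a, "-", b, call. = FALSE)
    }
    if (shared[i] == 0L) {
      category[i] <- "mtdna_precludes"
    } else if (!is.na(pv[i]) && pv[i] < alpha) {
      category[i] <- "mtdna_distinguishes"
    } else {
      category[i] <- "unresolved"
    }
  }
  outcomes <- data.frame(
    sample_id = records$sample_id,
    true_locality = records$true_locality,
    assigned_locality = records$assigned_locality,
    species_group = records$species_group,
    category = factor(category, levels = .TRI_CATEGORIES),
    shared = shared, fst = fstv, p = pv,
    stringsAsFactors = FALSE
  )
  counts <- table(outcomes$category)
  contingency <- table(
    category = outcomes$category,
    species_group = outcomes$species_group
  )
  new("TriangulationReport",
    outcomes = outcomes, alpha = alpha,
    categoryCounts = counts, contingency = contingency,
    nImproved = as.integer(
      counts["mtdna_precludes"] + counts["mtdna_distinguishes"]
    )
  )
}

#' Per-unit likelihood support for a batch of samples
#'
#' Confiscated material often arrives in batches from a single source.
#' For each candidate unit this scores the batch by the sum over samples of
#' the log smoothed frequency of the sample's haplotype in that unit
#' (add-one smoothing over the unit's haplotype counts, with the global
#' haplotype inventory as the support), and flags units for which the batch
#' contains a haplotype private to that unit. The likelihood form and its
#' smoothing are an extension built on the haplotype table, not a published
#' procedure.
#'
#' @param sampleIds character vector of batch sample ids (must be members of
#'   the table).
#' @param table a [HaplotypeTable-class].
#' @param candidateUnits locality codes to score (default: all).
#' @param level `"locality"` or `"country"`.
#' @return data.frame with columns `unit`, `log_score`,
#'   `n_private_hits`, `private_flag`, sorted by decreasing `log_score`.
#' @export
batchFrequencySupport <- function(sampleIds, table, candidateUnits = NULL,
                                  level = c("locality", "country")) {
  level <- match.arg(level)
  stopifnot(length(sampleIds) >= 1)
  counts <- haplotypeCounts(table, level = level)
  if (is.null(candidateUnits)) candidateUnits <- colnames(counts)
  if (!length(candidateUnits)) stop("no candidate units", call. = FALSE)
  memb <- rep(names(table@members), lengths(table@members))
  names(memb) <- unlist(table@members, use.names = FALSE)
  hap <- memb[sampleIds]
  if (anyNA(hap)) {
    stop("sample(s) absent from haplotype table: ",
      paste(sampleIds[is.na(hap)], collapse = ", "),
      call. = FALSE
    )
  }
  H <- nrow(counts)
  spread <- rowSums(counts > 0)
  res <- lapply(candidateUnits, function(u) {
    cu <- counts[, u]
    nU <- sum(cu)
    logp <- sum(log((cu[hap] + 1) / (nU + H)))
    priv <- sum(spread[hap] == 1 & cu[hap] > 0)
    data.frame(
      unit = u, log_score = logp, n_private_hits = priv,
      private_flag = priv > 0, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out[order(-out$log_score, out$unit), , drop = FALSE]
}

#' Write a triangulation report
#'
#' @param x a [TriangulationReport-class].
#' @param jsonPath path for the JSON summary (counts, contingency, improvement).
#' @param matrixPath optional path for a true-by-assigned category matrix TSV.
#' @return Invisibly, `x`.
#' @export
writeTriangulationReport <- function(x, jsonPath, matrixPath = NULL) {
  obj <- list(
    alpha = x@alpha,
    n_records = nrow(x@outcomes),
    category_counts = as.list(x@categoryCounts),
    contingency = as.data.frame(x@contingency),
    n_improved = x@nImproved
  )
  jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(matrixPath)) {
    mat <- with(x@outcomes, table(true_locality, assigned_locality, category))
    df <- as.data.frame(mat)
    df <- df[df$Freq > 0, , drop = FALSE]
    utils::write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Accessor: triangulation outcomes
#'
#' @param x a [TriangulationReport-class].
#' @return The per-sample outcomes data.frame.
#' @export
triangulationOutcomes <- function(x) {
  stopifnot(is(x, "TriangulationReport"))
  x@outcomes
}

#' Accessor: improvement fraction among mis-assigned records
#'
#' Fraction of mis-assigned records where mtDNA either precludes the wrong
#' locality or distinguishes the pair by haplotype frequencies.
#'
#' @param x a [TriangulationReport-class].
#' @return Numeric scalar in `[0, 1]` (NaN when nothing was mis-assigned).
#' @export
improvementFraction <- function(x) {
  stopifnot(is(x, "TriangulationReport"))
  mis <- sum(x@categoryCounts) - x@categoryCounts["nuclear_correct"]
  as.numeric(x@nImproved / mis)
}

setMethod("show", "TriangulationReport", function(object) {
  cat(sprintf(
    "TriangulationReport: %d record(s), alpha = %g\n",
    nrow(object@outcomes), object@alpha
  ))
  for (cat_ in names(object@categoryCounts)) {
    cat(sprintf("  %-20s %d\n", cat_, object@categoryCounts[[cat_]]))
  }
  mis <- sum(object@categoryCounts) - object@categoryCounts[["nuclear_correct"]]
  if (mis > 0) {
    cat(sprintf(
      "  mtDNA improves %d of %d mis-assigned (%.0f%%)\n",
      object@nImproved, mis, 100 * object@nImproved / mis
    ))
  }
})
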