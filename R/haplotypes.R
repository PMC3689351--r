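#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Find variable alignment columns
#'
#' A column is variable iff at least two distinct states among
#' `A, C, G, T, -` occur there; `N` never creates variability. The gap
#' character is a genuine fifth state (indels distinguish haplotypes).
#'
#' @param x an [MtAlignment-class].
#' @return Ascending integer vector of variable column indices.
#' @export
findVariableSites <- function(x) {
  stopifnot(is(x, "MtAlignment"))
  .variableColumns(.seqMatrix(x))
}

#' Collapse aligned sequences into unique haplotypes
#'
#' Groups samples whose sequences are identical at every variable column into
#' haplotypes, recording per-locality and per-country membership counts.
#' Sequences carrying `N` at variable columns are handled by the
#' missing-data policy:
#'
#' * `"strict"`: any sample with `N` at a variable column is excluded and
#'   counted in the exclusion report.
#' * `"resolve"` (default): such a sample is merged into an existing
#'   haplotype iff exactly one haplotype matches it at all of its non-`N`
#'   columns; otherwise (zero or several candidates) it is excluded. This is
#'   how partial voucher sequences (e.g. ones missing a trailing stretch of
#'   the control region) stay usable.
#'
#' Haplotype ids `H001, H002, ...` are assigned deterministically by
#' descending total count, ties broken by lexicographic sequence.
#'
#' @param x an [MtAlignment-class]; must be non-empty.
#' @param missingPolicy `"resolve"` or `"strict"`.
#' @return A [HaplotypeTable-class].
#' @examples
#' aln <- MtAlignment(
#'   c(s1 = "AAA", s2 = "AAA", s3 = "AAT", s4 = "GAT"),
#'   data.frame(
#'     sample_id = paste0("s", 1:4), locality = c("AA", "AA", "BB", "BB"),
#'     country = c("X", "X", "Y", "Y"), species = "savanna"
#'   )
#' )
#' tab <- collapseHaplotypes(aln)
#' nHaplotypes(tab) # 3
#' variableSites(tab) # columns 1 and 3
#' @export
collapseHaplotypes <- function(x, missingPolicy = c("resolve", "strict")) {
  stopifnot(is(x, "MtAlignment"))
  missingPolicy <- match.arg(missingPolicy)
  if (!length(x@seqs)) stop("empty dataset", call. = FALSE)
  m <- .seqMatrix(x)
  ids <- rownames(m)
  vs <- .variableColumns(m)
  vmat <- m[, vs, drop = FALSE]
  hasN <- if (length(vs)) rowSums(vmat == "N") > 0 else rep(FALSE, nrow(m))

  cleanIdx <- which(!hasN)
  if (!length(cleanIdx)) {
    stop("no sequence free of N at variable columns; nothing to collapse",
      call. = FALSE
    )
  }
  cleanKey <- .collapseRows(vmat[cleanIdx, , drop = FALSE])
  groups <- split(cleanIdx, cleanKey)

  # membership of ambiguous sequences under the resolve policy
  excluded <- integer()
  if (missingPolicy == "strict") {
    excluded <- which(hasN)
  } else if (any(hasN)) {
    keyMat <- do.call(rbind, lapply(groups, function(g) vmat[g[1], , drop = TRUE]))
    for (i in which(hasN)) {
      obs <- vmat[i, ]
      use <- obs != "N"
      hits <- which(vapply(seq_along(groups), function(k) {
        all(keyMat[k, use] == obs[use])
      }, logical(1)))
      if (length(hits) == 1L) {
        groups[[hits]] <- c(groups[[hits]], i)
      } else {
        excluded <- c(excluded, i)
      }
    }
  }

  # representative sequence: member with fewest Ns overall, then input order
  repSeq <- vapply(groups, function(g) {
    nn <- rowSums(m[g, , drop = FALSE] == "N")
    paste(m[g[order(nn, g)[1]], ], collapse = "")
  }, character(1))
  tot <- lengths(groups)
  ord <- order(-tot, repSeq)
  groups <- groups[ord]
  repSeq <- repSeq[ord]
  hapIds <- sprintf("H%03d", seq_along(groups))

  meta <- as.data.frame(x@sampleData)
  locs <- sort(unique(meta$locality))
  counts <- matrix(0L, nrow = length(groups), ncol = length(locs),
    dimnames = list(hapIds, locs)
  )
  members <- lapply(groups, function(g) ids[sort(g)])
  for (k in seq_along(groups)) {
    tb <- table(meta$locality[groups[[k]]])
    counts[k, names(tb)] <- as.integer(tb)
  }
  lc <- meta$country[match(locs, meta$locality)]
  names(lc) <- locs

  names(repSeq) <- hapIds
  names(members) <- hapIds
  new("HaplotypeTable",
    sequences = repSeq, members = members, counts = counts,
    localityCountry = lc, variableSites = as.integer(vs), frame = x@frame,
    nExcluded = length(excluded), excludedIds = ids[sort(excluded)]
  )
}

#' Collapse haplotypes within a reference window
#'
#' Equivalent to `collapseHaplotypes(extractRegion(x, refStart, refEnd))`:
#' haplotypes distinct over the full alignment may merge in the shorter
#' window (e.g. a short control-region segment shared across surveys).
#'
#' @inheritParams extractRegion
#' @inheritParams collapseHaplotypes
#' @return A [HaplotypeTable-class] over the windowed columns.
#' @export
haplotypeTableByRegion <- function(x, refStart, refEnd,
                                   missingPolicy = c("resolve", "strict")) {
  collapseHaplotypes(extractRegion(x, refStart, refEnd),
    missingPolicy = match.arg(missingPolicy)
  )
}

#' Write a haplotype table and its variable sites to TSV
#'
#' @param x a [HaplotypeTable-class].
#' @param hapPath output path for the haplotype table (id, sequence, total
#'   count, one column per locality).
#' @param sitesPath optional output path for the variable-site table
#'   (column, reference position, observed states).
#' @return Invisibly, `x`.
#' @export
writeHaplotypeTable <- function(x, hapPath, sitesPath = NULL) {
  df <- data.frame(
    hap_id = names(x@sequences), sequence = unname(x@sequences),
    total_count = unname(rowSums(x@counts)), stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(x@counts))
  utils::write.table(df, hapPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sitesPath)) {
    m <- .seqMatrix(x@sequences)
    states <- vapply(x@variableSites, function(j) {
      paste(sort(unique(setdiff(m[, j], "N"))), collapse = "/")
    }, character(1))
    sdf <- data.frame(
      column = x@variableSites,
      ref_position = x@frame@columnToRef[x@variableSites],
      states = states
    )
    utils::write.table(sdf, sitesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Accessors for HaplotypeTable
#'
#' @param x a [HaplotypeTable-class].
#' @param level `"locality"` or `"country"` for `haplotypeCounts`.
#' @return `nHaplotypes`: number of distinct haplotypes; `haplotypeCounts`:
#'   integer matrix haplotypes x units; `haplotypeSequences`: named character
#'   vector; `variableSites`: integer columns; `haplotypeMembers`: list of
#'   member sample ids.
#' @name HaplotypeTable-accessors
NULL

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("nHaplotypes", "HaplotypeTable", function(x) length(x@sequences))

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("haplotypeCounts", "HaplotypeTable", function(x, level = c("locality", "country")) {
  level <- match.arg(level)
  if (level == "locality") {
    return(x@counts)
  }
  ctry <- x@localityCountry[colnames(x@counts)]
  t(rowsum(t(x@counts), group = ctry))
})

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("haplotypeSequences", "HaplotypeTable", function(x) x@sequences)

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("variableSites", "HaplotypeTable", function(x) x@variableSites)

#' @rdname HaplotypeTable-accessors
#' @export
setMethod("haplotypeMembers", "HaplotypeTable", function(x) x@members)

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf(
    "HaplotypeTable: %d haplotype(s) from %d sample(s) (%d excluded)\n",
    length(object@sequences), sum(object@counts), object@nExcluded
  ))
  cat(sprintf(
    "  %d variable site(s); %d locality(ies), %d country(ies)\n",
    length(object@variableSites), ncol(object@counts),
    length(unique(object@localityCountry[colnames(object@counts)]))
  ))
})
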