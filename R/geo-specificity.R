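#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Geographic specificity of haplotypes
#'
#' For each unique haplotype, counts the number of geographic units
#' (localities or countries) where it was observed (its *spread*), and
#' summarizes: the fraction of unique haplotypes observed in exactly `k`
#' units, and the fraction of individuals carrying such haplotypes. Spread-1
#' haplotypes are *private*: detected at a single locality (or country) —
#' the key quantity for forensic provenance, since an individual carrying a
#' private haplotype can only have come from that unit's matriline range.
#'
#' Individuals excluded during collapsing are excluded from denominators
#' (their count is carried in the table).
#'
#' @param table a [HaplotypeTable-class].
#' @param level `"locality"` or `"country"`.
#' @return A list: `level`; `spread` (named integer per haplotype);
#'   `hapFractionBySpread` and `individualFractionBySpread` (named numeric,
#'   fractions summing to 1); `nUnitsWithPrivate`; `nHaplotypes`;
#'   `nIndividuals`.
#' @export
haplotypeSpecificity <- function(table, level = c("locality", "country")) {
  level <- match.arg(level)
  counts <- haplotypeCounts(table, level = level)
  if (anyNA(table@localityCountry[colnames(table@counts)])) {
    stop("country metadata missing for localities: ",
      paste(colnames(table@counts)[is.na(table@localityCountry[colnames(table@counts)])],
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  spread <- rowSums(counts > 0)
  indiv <- rowSums(counts)
  ks <- sort(unique(spread))
  hapFrac <- vapply(ks, function(k) mean(spread == k), numeric(1))
  indFrac <- vapply(ks, function(k) sum(indiv[spread == k]) / sum(indiv), numeric(1))
  names(hapFrac) <- names(indFrac) <- ks
  private <- counts[spread == 1, , drop = FALSE]
  list(
    level = level,
    spread = spread,
    hapFractionBySpread = hapFrac,
    individualFractionBySpread = indFrac,
    nUnitsWithPrivate = sum(colSums(private) > 0),
    nHaplotypes = nrow(counts),
    nIndividuals = sum(indiv)
  )
}

#' Locality-by-locality haplotype sharing matrix
#'
#' Entry `(a, b)` counts haplotypes observed in both units; the diagonal is
#' each unit's haplotype richness. Zero off-diagonal entries identify unit
#' pairs between which mtDNA alone precludes cross-assignment.
#'
#' @param table a [HaplotypeTable-class].
#' @param level `"locality"` or `"country"`.
#' @return Symmetric integer matrix with unit dimnames.
#' @export
sharingMatrix <- function(table, level = c("locality", "country")) {
  level <- match.arg(level)
  p <- haplotypeCounts(table, level = level) > 0
  m <- crossprod(p * 1L)
  storage.mode(m) <- "integer"
  m
}

#' Units possessing private haplotypes
#'
#' @param table a [HaplotypeTable-class].
#' @param level `"locality"` or `"country"`.
#' @return Character vector (sorted) of units carrying at least one
#'   haplotype found nowhere else.
#' @export
privateHaplotypeUnits <- function(table, level = c("locality", "country")) {
  level <- match.arg(level)
  counts <- haplotypeCounts(table, level = level)
  if (!nrow(counts)) {
    return(character())
  }
  spread <- rowSums(counts > 0)
  private <- counts[spread == 1, , drop = FALSE]
  sort(colnames(counts)[colSums(private) > 0])
}

#' Render a specificity report with whole-percent rounding
#'
#' Percentages are rounded half away from zero to whole percent, the
#' convention used when reporting e.g. "72% of haplotypes were found at only
#' a single locality"; full precision is retained in the report object
#' itself.
#'
#' @param report a list from [haplotypeSpecificity()].
#' @return data.frame with columns `spread`, `pct_haplotypes`,
#'   `pct_individuals`.
#' @export
formatSpecificity <- function(report) {
  pct <- function(x) {
    s <- sign(x * 100)
    s * floor(abs(x * 100) + 0.5)
  }
  data.frame(
    spread = as.integer(names(report$hapFractionBySpread)),
    pct_haplotypes = pct(report$hapFractionBySpread),
    pct_individuals = pct(report$individualFractionBySpread),
    row.names = NULL
  )
}
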