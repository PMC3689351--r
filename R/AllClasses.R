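#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

.MT_ALPHABET <- c("A", "C", "G", "T", "-", "N")
.SPECIES_LEVELS <- c("savanna", "forest", "hybrid_zone", "unknown")

#' ReferenceFrame: mapping between alignment columns and reference positions
#'
#' Records the reference genome interval that an alignment spans and, for every
#' alignment column, the corresponding reference position (`NA` for columns
#' that are gaps relative to the reference). Positions are 1-based inclusive,
#' as in "positions 11 750--16 006" style coordinates used for the savanna
#' elephant reference mitogenome.
#'
#' @slot referenceId single string naming the reference sequence.
#' @slot refStart,refEnd 1-based inclusive reference interval.
#' @slot columnToRef integer vector, one entry per alignment column; `NA`
#'   marks columns with no reference coordinate (reference gaps).
#' @exportClass ReferenceFrame
setClass("ReferenceFrame",
  representation(
    referenceId = "character",
    refStart = "integer",
    refEnd = "integer",
    columnToRef = "integer"
  )
)

setValidity("ReferenceFrame", function(object) {
  msg <- character()
  if (length(object@referenceId) != 1L) {
    msg <- c(msg, "referenceId must be a single string")
  }
  if (object@refStart >= object@refEnd) {
    msg <- c(msg, "refStart must be < refEnd")
  }
  m <- object@columnToRef[!is.na(object@columnToRef)]
  if (length(m) && any(diff(m) < 0)) {
    msg <- c(msg, "columnToRef must be monotone non-decreasing on non-gap columns")
  }
  if (length(m) && (min(m) < object@refStart || max(m) > object@refEnd)) {
    msg <- c(msg, "columnToRef values must lie within [refStart, refEnd]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceFrame
#'
#' @param referenceId reference sequence identifier.
#' @param refStart,refEnd 1-based inclusive reference interval.
#' @param columnToRef optional integer mapping of alignment column to
#'   reference position; defaults to the contiguous run `refStart:refEnd`.
#' @return A [ReferenceFrame-class] object.
#' @export
ReferenceFrame <- function(referenceId, refStart, refEnd, columnToRef = NULL) {
  if (is.null(columnToRef)) columnToRef <- seq.int(refStart, refEnd)
  new("ReferenceFrame",
    referenceId = as.character(referenceId),
    refStart = as.integer(refStart), refEnd = as.integer(refEnd),
    columnToRef = as.integer(columnToRef)
  )
}

#' MtAlignment: an aligned mtDNA dataset with sample metadata
#'
#' The entry-stage container of the pipeline: a fixed-width multiple sequence
#' alignment (alphabet `A,C,G,T,-,N`) stored as a
#' [Biostrings::DNAStringSet], per-sample metadata (2-letter locality code,
#' country, species group), and the [ReferenceFrame-class] tying alignment
#' columns to reference mitogenome positions.
#'
#' @slot seqs `DNAStringSet`, all of equal width, names are unique sample ids.
#' @slot sampleData `DataFrame` with columns `locality`, `country`, `species`;
#'   rownames are the sample ids, in the same order as `seqs`.
#' @slot frame a [ReferenceFrame-class].
#' @exportClass MtAlignment
setClass("MtAlignment",
  representation(
    seqs = "DNAStringSet",
    sampleData = "DataFrame",
    frame = "ReferenceFrame"
  )
)

setValidity("MtAlignment", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (n > 0) {
    w <- Biostrings::width(object@seqs)
    if (length(unique(w)) != 1L) {
      msg <- c(msg, "all sequences must have identical alignment width")
    } else if (w[1] != length(object@frame@columnToRef)) {
      msg <- c(msg, "alignment width must match frame columnToRef length")
    }
    ids <- names(object@seqs)
    if (is.null(ids) || anyDuplicated(ids)) {
      msg <- c(msg, "sample ids must be present and unique")
    }
    if (!identical(ids, rownames(object@sampleData))) {
      msg <- c(msg, "sampleData rownames must match sequence names in order")
    }
  }
  req <- c("locality", "country", "species")
  if (!all(req %in% colnames(object@sampleData))) {
    msg <- c(msg, "sampleData needs columns locality, country, species")
  } else if (n > 0) {
    lc <- unique(data.frame(
      locality = object@sampleData$locality,
      country = object@sampleData$country
    ))
    if (anyDuplicated(lc$locality)) {
      msg <- c(msg, "each locality must map to exactly one country")
    }
    if (!all(object@sampleData$species %in% .SPECIES_LEVELS)) {
      msg <- c(msg, sprintf(
        "species must be one of %s", paste(.SPECIES_LEVELS, collapse = ", ")
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeTable: unique haplotypes with geographic membership counts
#'
#' Result of collapsing an alignment: distinct sequences (haplotypes) with the
#' samples carrying each, counts per locality, the locality-to-country map,
#' and the ordered list of variable alignment columns. Haplotype ids are
#' assigned deterministically (descending total count, ties broken by
#' lexicographic sequence).
#'
#' @slot sequences named character vector of representative full-length
#'   sequences; names are haplotype ids.
#' @slot members list (parallel to `sequences`) of member sample ids.
#' @slot counts integer matrix, haplotypes x localities.
#' @slot localityCountry named character vector mapping locality -> country.
#' @slot variableSites ascending integer vector of variable alignment columns.
#' @slot frame the [ReferenceFrame-class] of the source alignment.
#' @slot nExcluded number of samples excluded under the missing-data policy.
#' @slot excludedIds their sample ids.
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(
    sequences = "character",
    members = "list",
    counts = "matrix",
    localityCountry = "character",
    variableSites = "integer",
    frame = "ReferenceFrame",
    nExcluded = "integer",
    excludedIds = "character"
  )
)

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  h <- length(object@sequences)
  if (length(object@members) != h) msg <- c(msg, "members/sequences length mismatch")
  if (h > 0 && nrow(object@counts) != h) msg <- c(msg, "counts rows must match haplotypes")
  if (h > 0 && anyDuplicated(object@sequences)) {
    msg <- c(msg, "haplotype sequences must be pairwise distinct")
  }
  if (h > 0) {
    tot <- rowSums(object@counts)
    if (!all(tot == lengths(object@members))) {
      msg <- c(msg, "per-haplotype counts must sum to member set size")
    }
  }
  if (!all(colnames(object@counts) %in% names(object@localityCountry))) {
    msg <- c(msg, "every locality must have a country in localityCountry")
  }
  if (is.unsorted(object@variableSites, strictly = TRUE) && length(object@variableSites) > 1) {
    msg <- c(msg, "variableSites must be strictly ascending")
  }
  if (length(msg)) msg else TRUE
})

#' DiagnosticKey: hierarchical clade/subclade diagnostic-site key
#'
#' A decision table of diagnostic alignment columns. Clade-level sites are
#' evaluated first, assigning a sequence to one of the top-level clades; then
#' subclade-level sites within the assigned clade. `fixed = TRUE` sites carry
#' states fully fixed within the group they label (no exceptions on the
#' training data) and are the only sites that can declare a conflict;
#' `fixed = FALSE` sites (group-specific polymorphisms with within-group
#' exceptions) contribute votes only.
#'
#' @slot sites data.frame with columns `column`, `refPosition`, `level`
#'   ("clade" or "subclade"), `parent`, `fixed`.
#' @slot stateMaps list (parallel to rows of `sites`) of named character
#'   vectors mapping a base state to the child label it supports.
#' @slot hierarchy named list: clade label -> character vector of subclades.
#' @exportClass DiagnosticKey
setClass("DiagnosticKey",
  representation(
    sites = "data.frame",
    stateMaps = "list",
    hierarchy = "list"
  )
)

setValidity("DiagnosticKey", function(object) {
  msg <- character()
  req <- c("column", "refPosition", "level", "parent", "fixed")
  if (!all(req %in% colnames(object@sites))) {
    msg <- c(msg, "sites must have columns column, refPosition, level, parent, fixed")
  } else {
    if (length(object@stateMaps) != nrow(object@sites)) {
      msg <- c(msg, "stateMaps must parallel sites rows")
    }
    if (!all(object@sites$level %in% c("clade", "subclade"))) {
      msg <- c(msg, "level must be 'clade' or 'subclade'")
    }
    subs <- unlist(object@hierarchy, use.names = FALSE)
    cl <- names(object@hierarchy)
    ok <- vapply(seq_along(object@stateMaps), function(i) {
      lab <- object@stateMaps[[i]]
      if (object@sites$level[i] == "clade") all(lab %in% cl) else all(lab %in% subs)
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "stateMap labels must be declared clade/subclade labels")
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeNetwork: a median-joining haplotype network
#'
#' Nodes are observed haplotypes plus inferred median vectors (frequency 0),
#' each carrying its sequence over the variable-site columns; edges carry the
#' number of differing variable sites. The underlying graph is an
#' [igraph::igraph] with vertex attributes `name`, `kind`
#' ("observed"/"median"), `frequency`, `sequence`, and edge attribute
#' `weight`.
#'
#' @slot graph the igraph object.
#' @slot epsilon the tolerance parameter used during construction.
#' @slot variableSites alignment columns the node sequences are restricted to.
#' @slot cost minimum-spanning-tree cost over the final node set (total
#'   mutational steps needed to connect the network).
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(
    graph = "ANY",
    epsilon = "integer",
    variableSites = "integer",
    cost = "numeric"
  )
)

#' FstResult: pairwise haplotype F_ST with permutation p-value
#'
#' @slot unitA,unitB locality (or country) codes.
#' @slot fst observed haplotype-identity F_ST (may be negative).
#' @slot pValue permutation p-value, `(1 + #{perm >= obs}) / (1 + n)`.
#' @slot nPermutations,seed the test configuration.
#' @slot nA,nB sample sizes.
#' @exportClass FstResult
setClass("FstResult",
  representation(
    unitA = "character", unitB = "character",
    fst = "numeric", pValue = "numeric",
    nPermutations = "integer", seed = "integer",
    nA = "integer", nB = "integer"
  )
)

setValidity("FstResult", function(object) {
  msg <- character()
  if (object@fst > 1 + 1e-12) msg <- c(msg, "fst must be <= 1")
  if (object@pValue < 0 || object@pValue > 1) msg <- c(msg, "pValue must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' FstMatrix: all pairwise F_ST values and permutation p-values
#'
#' @slot units ordered unit (locality) codes.
#' @slot fst,pvalues symmetric matrices (diagonal fst = 0, p = 1); `NA`
#'   marks pairs that failed preconditions (fewer than 2 individuals).
#' @slot nPermutations,seed configuration used for every pair.
#' @exportClass FstMatrix
setClass("FstMatrix",
  representation(
    units = "character",
    fst = "matrix",
    pvalues = "matrix",
    nPermutations = "integer",
    seed = "integer"
  )
)

setValidity("FstMatrix", function(object) {
  msg <- character()
  k <- length(object@units)
  if (!all(dim(object@fst) == c(k, k)) || !all(dim(object@pvalues) == c(k, k))) {
    msg <- c(msg, "matrix dimensions must match units")
  } else {
    if (!isTRUE(all.equal(object@fst, t(object@fst)))) msg <- c(msg, "fst must be symmetric")
    d <- diag(object@fst)
    if (any(!is.na(d) & d != 0)) msg <- c(msg, "fst diagonal must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' TriangulationReport: per-sample provenance evidence categories
#'
#' Combines a nuclear assignment table with mtDNA haplotype sharing and
#' F_ST significance. Categories: `nuclear_correct` (assignment matched the
#' true locality), `mtdna_precludes` (no haplotype shared between true and
#' assigned locality), `mtdna_distinguishes` (haplotypes shared but F_ST
#' between the pair significant at `alpha`), `unresolved`.
#'
#' @slot outcomes data.frame: `sample_id`, `true_locality`,
#'   `assigned_locality`, `species_group`, `category`, `shared`, `fst`, `p`.
#' @slot alpha significance level applied to permutation p-values.
#' @slot categoryCounts table of category counts.
#' @slot contingency category x species_group contingency table.
#' @slot nImproved count of mis-assignments resolved by mtDNA
#'   (`mtdna_precludes + mtdna_distinguishes`).
#' @exportClass TriangulationReport
setClass("TriangulationReport",
  representation(
    outcomes = "data.frame",
    alpha = "numeric",
    categoryCounts = "table",
    contingency = "table",
    nImproved = "integer"
  )
)

setValidity("TriangulationReport", function(object) {
  if (sum(object@categoryCounts) != nrow(object@outcomes)) {
    "category counts must sum to the number of records"
  } else TRUE
})
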