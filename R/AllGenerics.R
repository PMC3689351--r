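#' @include AllClasses.R
NULL

#' @rdname MtAlignment-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MtAlignment-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname MtAlignment-accessors
#' @export
setGeneric("referenceFrame", function(x) standardGeneric("referenceFrame"))

#' @rdname MtAlignment-accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' Restrict an alignment to a reference interval
#'
#' @param x an [MtAlignment-class].
#' @param refStart,refEnd 1-based inclusive reference positions; the interval
#'   must lie within the alignment's [ReferenceFrame-class].
#' @return An [MtAlignment-class] over the alignment columns whose reference
#'   position falls inside the interval (columns with no reference position,
#'   i.e. reference gaps, are retained when flanked by in-interval columns so
#'   coordinates stay translatable).
#' @export
setGeneric("extractRegion", function(x, refStart, refEnd) standardGeneric("extractRegion"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("haplotypeCounts", function(x, level = c("locality", "country")) {
  standardGeneric("haplotypeCounts")
})

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("haplotypeSequences", function(x) standardGeneric("haplotypeSequences"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("variableSites", function(x) standardGeneric("variableSites"))

#' @rdname HaplotypeTable-accessors
#' @export
setGeneric("haplotypeMembers", function(x) standardGeneric("haplotypeMembers"))

#' @rdname HaplotypeNetwork-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname HaplotypeNetwork-accessors
#' @export
setGeneric("networkCost", function(x) standardGeneric("networkCost"))

#' @rdname FstMatrix-accessors
#' @export
setGeneric("fstValues", function(x) standardGeneric("fstValues"))

#' @rdname FstMatrix-accessors
#' @export
setGeneric("fstPValues", function(x) standardGeneric("fstPValues"))
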