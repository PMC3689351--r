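#' @include AllClasses.R AllGenerics.R utils.R
NULL

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# uppercase, map IUPAC ambiguity codes (other than N) to N; returns list with
# cleaned character vector and the ids of records that contained ambiguities
.cleanSequences <- function(seqs, ids) {
  seqs <- toupper(seqs)
  pat <- paste0("[", paste(.IUPAC_AMBIG, collapse = ""), "]")
  hit <- grepl(pat, seqs)
  if (any(hit)) seqs[hit] <- gsub(pat, "N", seqs[hit])
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("invalid characters (outside A,C,G,T,-,N and IUPAC codes) in: ",
      paste(ids[bad], collapse = ", "),
      call. = FALSE
    )
  }
  list(seqs = seqs, ambiguous = ids[hit])
}

#' Construct an MtAlignment from sequences and metadata
#'
#' Uppercases bases and maps IUPAC ambiguity codes other than `N` to `N`
#' (with a warning naming the affected records). Sequences must all share one
#' alignment width.
#'
#' @param seqs named character vector or `DNAStringSet` of aligned sequences.
#' @param sampleData data.frame or `DataFrame` with columns `locality`,
#'   `country`, `species` and rownames (or a `sample_id` column) matching the
#'   sequence names.
#' @param frame optional [ReferenceFrame-class]; defaults to a contiguous
#'   frame `1..L` on reference `"unspecified"`.
#' @return An [MtAlignment-class].
#' @export
MtAlignment <- function(seqs, sampleData, frame = NULL) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    dup <- if (is.null(ids)) "<unnamed>" else unique(ids[duplicated(ids)])
    stop("duplicate or missing sample ids: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    ref <- as.integer(names(which.max(table(w))))
    off <- ids[w != ref]
    stop("alignment length mismatch for record(s): ", paste(off, collapse = ", "),
      call. = FALSE
    )
  }
  cl <- .cleanSequences(seqs, ids)
  if (length(cl$ambiguous)) {
    warning("IUPAC ambiguity codes converted to N in: ",
      paste(cl$ambiguous, collapse = ", "),
      call. = FALSE
    )
  }
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData)) {
    rownames(sampleData) <- sampleData$sample_id
    sampleData$sample_id <- NULL
  }
  missingMeta <- setdiff(ids, rownames(sampleData))
  if (length(missingMeta)) {
    stop("metadata missing for sequence id(s): ", paste(missingMeta, collapse = ", "),
      call. = FALSE
    )
  }
  sampleData <- sampleData[ids, , drop = FALSE]
  bad <- !(sampleData$species %in% .SPECIES_LEVELS)
  if (any(bad)) {
    warning("unrecognized species label(s) set to 'unknown' for: ",
      paste(ids[bad], collapse = ", "),
      call. = FALSE
    )
    sampleData$species[bad] <- "unknown"
  }
  if (is.null(frame)) {
    frame <- ReferenceFrame("unspecified", 1L, max(w[1], 2L),
      columnToRef = seq_len(w[1])
    )
  }
  new("MtAlignment",
    seqs = Biostrings::DNAStringSet(setNames(cl$seqs, ids)),
    sampleData = DataFrame(sampleData),
    frame = frame
  )
}

#' Read an aligned mtDNA dataset from FASTA + metadata TSV
#'
#' @param fastaPath path to an aligned FASTA file (wrapped or unwrapped).
#' @param metadataPath path to a tab-separated table with header columns
#'   `sample_id`, `locality`, `country`, `species`.
#' @param frame optional [ReferenceFrame-class] for the alignment columns.
#' @return An [MtAlignment-class]. Fails if any sequence lacks a metadata
#'   record, ids are duplicated, or records differ in length.
#' @examples
#' fa <- system.file("extdata", "toy_alignment.fasta", package = "mtprov")
#' tsv <- system.file("extdata", "toy_metadata.tsv", package = "mtprov")
#' aln <- readMtAlignment(fa, tsv)
#' @export
readMtAlignment <- function(fastaPath, metadataPath, frame = NULL) {
  ss <- Biostrings::readBStringSet(fastaPath)
  meta <- utils::read.delim(metadataPath,
    sep = "\t", header = TRUE,
    colClasses = "character"
  )
  req <- c("sample_id", "locality", "country", "species")
  if (!all(req %in% colnames(meta))) {
    stop("metadata must have header columns: ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
      paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  # FASTA headers may carry descriptions after whitespace; keep the first token
  names(ss) <- sub("\\s.*$", "", names(ss))
  MtAlignment(as.character(ss), meta, frame = frame)
}

#' Write an MtAlignment to FASTA + metadata TSV
#'
#' Inverse of [readMtAlignment()]: writing then re-reading reproduces the
#' sequences and metadata exactly.
#'
#' @param x an [MtAlignment-class].
#' @param fastaPath,metadataPath output paths.
#' @return Invisibly, `x`.
#' @export
writeMtAlignment <- function(x, fastaPath, metadataPath) {
  Biostrings::writeXStringSet(x@seqs, fastaPath)
  meta <- as.data.frame(x@sampleData)
  meta <- cbind(sample_id = rownames(meta), meta)
  utils::write.table(meta, metadataPath,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(x)
}

#' Infer sample metadata from id prefixes
#'
#' Voucher sequence names often encode the sampling locality as a prefix of
#' the sample id (e.g. `KR0001` for an elephant from Kruger). This fills the
#' locality from the first `prefixLength` letters of each id and the country
#' from a supplied lookup; prefixes absent from the lookup yield country and
#' species `"unknown"` with a warning.
#'
#' @param x an [MtAlignment-class].
#' @param prefixLength number of leading characters encoding the locality.
#' @param localityCountry named character vector: locality code -> country.
#' @param localitySpecies optional named character vector: locality code ->
#'   species group (one of `savanna`, `forest`, `hybrid_zone`, `unknown`).
#' @return `x` with its sample metadata replaced by the inferred table.
#' @export
inferSampleMetadata <- function(x, prefixLength = 2L, localityCountry = character(),
                                localitySpecies = NULL) {
  stopifnot(is(x, "MtAlignment"), prefixLength >= 1L)
  ids <- sampleIds(x)
  loc <- substr(ids, 1L, prefixLength)
  country <- unname(localityCountry[loc])
  unknown <- is.na(country)
  if (any(unknown)) {
    warning("no country lookup for prefix(es): ",
      paste(unique(loc[unknown]), collapse = ", "),
      call. = FALSE
    )
    country[unknown] <- "unknown"
  }
  species <- rep("unknown", length(ids))
  if (!is.null(localitySpecies)) {
    sp <- unname(localitySpecies[loc])
    species[!is.na(sp)] <- sp[!is.na(sp)]
  }
  meta <- data.frame(
    locality = loc, country = country, species = species,
    row.names = ids, stringsAsFactors = FALSE
  )
  initialize(x, sampleData = DataFrame(meta))
}

#' @describeIn extractRegion restrict to the columns whose reference position
#'   lies in `[refStart, refEnd]`, keeping interior reference-gap columns.
#' @export
setMethod("extractRegion", "MtAlignment", function(x, refStart, refEnd) {
  fr <- x@frame
  refStart <- as.integer(refStart)
  refEnd <- as.integer(refEnd)
  if (refStart > refEnd || refStart < fr@refStart || refEnd > fr@refEnd) {
    stop(sprintf(
      "interval [%d, %d] outside reference frame [%d, %d]",
      refStart, refEnd, fr@refStart, fr@refEnd
    ), call. = FALSE)
  }
  inWin <- !is.na(fr@columnToRef) & fr@columnToRef >= refStart &
    fr@columnToRef <= refEnd
  if (!any(inWin)) stop("no alignment columns in requested interval", call. = FALSE)
  cols <- seq.int(min(which(inWin)), max(which(inWin)))
  seqs <- as.character(Biostrings::subseq(x@seqs,
    start = cols[1], end = cols[length(cols)]
  ))
  newFrame <- new("ReferenceFrame",
    referenceId = fr@referenceId,
    refStart = refStart, refEnd = refEnd,
    columnToRef = fr@columnToRef[cols]
  )
  initialize(x,
    seqs = Biostrings::DNAStringSet(seqs),
    frame = newFrame
  )
})

#' Accessors for MtAlignment
#'
#' @param x an [MtAlignment-class].
#' @return `sampleIds`: character vector of ids; `sampleData`: the metadata
#'   `DataFrame`; `referenceFrame`: the [ReferenceFrame-class];
#'   `alignmentWidth`: the shared alignment length.
#' @name MtAlignment-accessors
NULL

#' @rdname MtAlignment-accessors
#' @export
setMethod("sampleIds", "MtAlignment", function(x) names(x@seqs))

#' @rdname MtAlignment-accessors
#' @export
setMethod("sampleData", "MtAlignment", function(x) x@sampleData)

#' @rdname MtAlignment-accessors
#' @export
setMethod("referenceFrame", "MtAlignment", function(x) x@frame)

#' @rdname MtAlignment-accessors
#' @export
setMethod("alignmentWidth", "MtAlignment", function(x) {
  if (!length(x@seqs)) 0L else Biostrings::width(x@seqs)[1]
})

#' @rdname MtAlignment-accessors
#' @export
setMethod("length", "MtAlignment", function(x) length(x@seqs))

#' Subset an MtAlignment by sample
#'
#' @param x an [MtAlignment-class].
#' @param i sample indices, ids, or a logical vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MtAlignment", function(x, i, j, ..., drop = FALSE) {
  initialize(x, seqs = x@seqs[i], sampleData = x@sampleData[i, , drop = FALSE])
})

setMethod("show", "MtAlignment", function(object) {
  fr <- object@frame
  cat(sprintf(
    "MtAlignment: %d sample(s), %d columns\n", length(object@seqs),
    alignmentWidth(object)
  ))
  cat(sprintf(
    "  reference %s:%d-%d\n", fr@referenceId, fr@refStart,
    fr@refEnd
  ))
  if (length(object@seqs)) {
    cat(sprintf(
      "  localities: %s\n",
      paste(sort(unique(object@sampleData$locality)), collapse = " ")
    ))
  }
})
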