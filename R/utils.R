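#' @include AllClasses.R
NULL

# character matrix (samples x columns) from an MtAlignment or character vector
.seqMatrix <- function(x) {
  if (is(x, "MtAlignment")) {
    s <- as.character(x@seqs)
  } else {
    s <- as.character(x)
  }
  if (!length(s)) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  m <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
    nrow = length(s), byrow = TRUE
  )
  rownames(m) <- names(s)
  m
}

.collapseRows <- function(m) apply(m, 1L, paste, collapse = "")

# variable columns: >=2 distinct states among {A,C,G,T,-}; N never counts
.variableColumns <- function(m) {
  if (!nrow(m) || !ncol(m)) {
    return(integer())
  }
  which(vapply(seq_len(ncol(m)), function(j) {
    st <- unique(m[, j])
    length(setdiff(st, "N")) >= 2L
  }, logical(1)))
}

# translate reference positions to alignment columns under a frame (NA if absent)
.refToColumn <- function(frame, refPositions) {
  match(as.integer(refPositions), frame@columnToRef)
}

# deterministic 32-bit sub-seed from a master seed and integer tokens
.subSeed <- function(seed, ...) {
  tok <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (t in tok) s <- (s * 7919 + (t %% 2147483647) + 13) %% 2147483647
  as.integer(s)
}
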