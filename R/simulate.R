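#' @include AllClasses.R AllGenerics.R utils.R diagnostic-key.R
NULL

.F_SUBCLADES <- c(
  "western", "west-central", "north-central", "east-central", "south-central"
)
.S_SUBCLADES <- c("northern-savanna", "savanna-wide", "southeast-savanna")

.localityCodes <- function(n) {
  grid <- expand.grid(b = LETTERS, a = LETTERS, stringsAsFactors = FALSE)
  paste0(grid$a, grid$b)[seq_len(n)]
}

#' Simulation configuration for matrilocal mtDNA datasets
#'
#' Encodes the structure the analysis assumes: two deep clades (`F`, `S`)
#' split into subclades (5 + 3 by default) with fixed diagnostic sites
#' planted on every internal branch; locality-restricted haplotype pools
#' with a controlled private-haplotype fraction; geometric per-locality
#' haplotype frequency skew; and a nuclear assignment error process
#' independent of mtDNA subclade. Defaults emulate a 22-locality,
#' ~660-sample voucher collection over a 4258-column alignment.
#'
#' @param seed integer RNG seed.
#' @param subcladesPerClade integer pair: subclades within F and within S.
#' @param L alignment length (columns).
#' @param nFixedSitesPerSplit diagnostic mutations planted per internal
#'   branch (these become the recoverable key).
#' @param nLocalities number of sampling localities.
#' @param homeSubclade optional character vector (length `nLocalities`)
#'   giving each locality's home subclade; defaults to a balanced cycle over
#'   the eight subclades so every subclade region holds at least two
#'   localities.
#' @param countrySizes integer partition of `nLocalities` into countries.
#' @param samplesPerLocality individuals sampled per locality; must be at
#'   least `2 * haplotypesPerLocality + 2` so every pool haplotype can be
#'   observed.
#' @param haplotypesPerLocality haplotype richness each locality contributes.
#' @param privateFraction probability `p` that a pool haplotype is private
#'   to its locality (otherwise it is planted in one additional locality of
#'   the same subclade region), so the expected spread-1 haplotype fraction
#'   equals `p`.
#' @param withinSubcladeMutations singleton mutations distinguishing each
#'   haplotype from its subclade founder.
#' @param geomRatio geometric ratio of the haplotype frequency skew.
#' @param missingRate per-base probability of masking to `N`.
#' @param nuclearMisassignmentRate probability a sample's nuclear assignment
#'   points to a uniformly random wrong locality.
#' @param infiniteSites when `TRUE` (default) every mutation hits an unused
#'   column; set `FALSE` to allow homoplasy for network stress tests.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      subcladesPerClade = c(5L, 3L),
                      L = 4258L,
                      nFixedSitesPerSplit = 2L,
                      nLocalities = 22L,
                      homeSubclade = NULL,
                      countrySizes = c(3L, 2L, 4L, 3L, 2L, rep(1L, 8L)),
                      samplesPerLocality = 30L,
                      haplotypesPerLocality = 6L,
                      privateFraction = 0.72,
                      withinSubcladeMutations = 4L,
                      geomRatio = 0.5,
                      missingRate = 0,
                      nuclearMisassignmentRate = 0.452,
                      infiniteSites = TRUE) {
  subclades <- c(
    .F_SUBCLADES[seq_len(subcladesPerClade[1])],
    .S_SUBCLADES[seq_len(subcladesPerClade[2])]
  )
  if (is.null(homeSubclade)) {
    homeSubclade <- rep(subclades, length.out = nLocalities)
    homeSubclade <- sort(homeSubclade) # contiguous regions, balanced sizes
  }
  stopifnot(
    length(homeSubclade) == nLocalities,
    all(homeSubclade %in% subclades),
    sum(countrySizes) == nLocalities,
    privateFraction >= 0, privateFraction <= 1,
    missingRate >= 0, missingRate < 1,
    nuclearMisassignmentRate >= 0, nuclearMisassignmentRate <= 1,
    nFixedSitesPerSplit >= 1, haplotypesPerLocality >= 1,
    geomRatio > 0, geomRatio <= 1
  )
  if (samplesPerLocality < 2L * haplotypesPerLocality + 2L) {
    stop("samplesPerLocality must be >= 2 * haplotypesPerLocality + 2",
      call. = FALSE
    )
  }
  if (privateFraction < 1) {
    regionSizes <- table(homeSubclade)
    if (any(regionSizes[unique(homeSubclade)] < 2L)) {
      stop("with privateFraction < 1 every used subclade region needs >= 2 localities",
        call. = FALSE
      )
    }
  }
  hierarchy <- list(
    F = .F_SUBCLADES[seq_len(subcladesPerClade[1])],
    S = .S_SUBCLADES[seq_len(subcladesPerClade[2])]
  )
  cfg <- list(
    seed = as.integer(seed), subcladesPerClade = as.integer(subcladesPerClade),
    L = as.integer(L), nFixedSitesPerSplit = as.integer(nFixedSitesPerSplit),
    nLocalities = as.integer(nLocalities), homeSubclade = homeSubclade,
    countrySizes = as.integer(countrySizes),
    samplesPerLocality = as.integer(samplesPerLocality),
    haplotypesPerLocality = as.integer(haplotypesPerLocality),
    privateFraction = privateFraction,
    withinSubcladeMutations = as.integer(withinSubcladeMutations),
    geomRatio = geomRatio, missingRate = missingRate,
    nuclearMisassignmentRate = nuclearMisassignmentRate,
    infiniteSites = isTRUE(infiniteSites), hierarchy = hierarchy
  )
  # total mutation budget must fit the alignment under infinite sites
  budget <- 2L * cfg$nFixedSitesPerSplit +
    sum(subcladesPerClade) * cfg$nFixedSitesPerSplit +
    nLocalities * haplotypesPerLocality * cfg$withinSubcladeMutations
  if (cfg$infiniteSites && budget > cfg$L) {
    stop("alignment length L too small for the mutation budget (", budget, ")",
      call. = FALSE
    )
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path config file; keys are the arguments of [simConfig()].
#' @return A `SimConfig`.
#' @export
readSimConfig <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  do.call(simConfig, obj)
}

# draw with local RNG state so callers' streams are untouched
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv())) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate a matrilocal mtDNA voucher dataset
#'
#' Builds a two-clade, eight-subclade haplotype genealogy with
#' `nFixedSitesPerSplit` diagnostic mutations planted on each internal
#' branch, then populates locality haplotype pools: each pool slot creates a
#' locality-private haplotype with probability `privateFraction`, otherwise
#' a haplotype planted in the slot's locality plus one other locality of the
#' same subclade region. Haplotypes acquire `withinSubcladeMutations`
#' singleton mutations each (infinite-sites by default). Individuals are
#' drawn with a geometric frequency skew over a randomly permuted pool, with
#' one guaranteed carrier per pool haplotype (pool richness is the observed
#' richness, as voucher tables report it); bases are masked to `N` at
#' `missingRate`. Fully reproducible from the seed.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @param seed optional override of `config$seed`.
#' @return A list: `alignment` (an [MtAlignment-class]), `truth` (list with
#'   per-sample `subclade`/`locality`/`haplotype`, the haplotype registry,
#'   the generating [DiagnosticKey-class], the hierarchy, and per-locality
#'   home subclades).
#' @export
simulateMtdna <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(seed, {
    L <- config$L
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, L, replace = TRUE)
    freeCols <- sample.int(L) # pre-shuffled column supply (infinite sites)
    colPtr <- 0L
    takeCols <- function(k) {
      if (config$infiniteSites) {
        cols <- freeCols[colPtr + seq_len(k)]
        colPtr <<- colPtr + k
        cols
      } else {
        sample.int(L, k, replace = TRUE)
      }
    }
    mutate <- function(seqvec, cols) {
      for (cc in cols) {
        seqvec[cc] <- sample(setdiff(bases, seqvec[cc]), 1L)
      }
      seqvec
    }

    hierarchy <- config$hierarchy
    keySites <- list()
    keyMaps <- list()
    planted <- function(col, anc, der, level, parent, map) {
      keySites[[length(keySites) + 1L]] <<- data.frame(
        column = col, refPosition = 11749L + col, level = level,
        parent = parent, fixed = TRUE, stringsAsFactors = FALSE
      )
      keyMaps[[length(keyMaps) + 1L]] <<- map
    }

    cladeFounder <- list()
    for (cl in c("F", "S")) {
      cols <- takeCols(config$nFixedSitesPerSplit)
      fseq <- mutate(root, cols)
      for (cc in cols) {
        other <- setdiff(c("F", "S"), cl)
        mp <- setNames(c(cl, other), c(fseq[cc], root[cc]))
        planted(cc, root[cc], fseq[cc], "clade", "root", mp)
      }
      cladeFounder[[cl]] <- fseq
    }
    subFounder <- list()
    for (cl in c("F", "S")) {
      for (sc in hierarchy[[cl]]) {
        cols <- takeCols(config$nFixedSitesPerSplit)
        sseq <- mutate(cladeFounder[[cl]], cols)
        for (cc in cols) {
          mp <- setNames(sc, sseq[cc])
          planted(cc, cladeFounder[[cl]][cc], sseq[cc], "subclade", cl, mp)
        }
        subFounder[[sc]] <- sseq
      }
    }

    locs <- .localityCodes(config$nLocalities)
    home <- setNames(config$homeSubclade, locs)
    country <- setNames(
      rep(sprintf("C%02d", seq_along(config$countrySizes)), config$countrySizes),
      locs
    )
    cladeOfSub <- setNames(
      rep(names(hierarchy), lengths(hierarchy)),
      unlist(hierarchy, use.names = FALSE)
    )
    speciesOf <- setNames(
      ifelse(cladeOfSub[home] == "F", "forest", "savanna"), locs
    )

    # haplotype registry and per-locality pools
    hapSeq <- list()
    hapSub <- character()
    hapLocs <- list()
    pools <- setNames(vector("list", length(locs)), locs)
    incoming <- setNames(integer(length(locs)), locs)
    H <- config$haplotypesPerLocality
    newHap <- function(sub, where) {
      sq <- mutate(subFounder[[sub]], takeCols(config$withinSubcladeMutations))
      id <- sprintf("sim%04d", length(hapSeq) + 1L)
      hapSeq[[id]] <<- sq
      hapSub[id] <<- sub
      hapLocs[[id]] <<- where
      id
    }
    for (l in locs) {
      region <- setdiff(locs[home == home[l]], l)
      for (slot in seq_len(H)) {
        if (stats::runif(1) < config$privateFraction || !length(region)) {
          id <- newHap(home[l], l)
          pools[[l]] <- c(pools[[l]], id)
        } else {
          open <- region[incoming[region] < H]
          partner <- if (length(open)) {
            open[sample.int(length(open), 1L)]
          } else {
            region[sample.int(length(region), 1L)]
          }
          id <- newHap(home[l], c(l, partner))
          pools[[l]] <- c(pools[[l]], id)
          pools[[partner]] <- c(pools[[partner]], id)
          incoming[partner] <- incoming[partner] + 1L
        }
      }
    }

    # individuals: one guaranteed carrier per pool haplotype, remainder drawn
    # with geometric skew over a random pool permutation
    seqs <- character()
    sampleLoc <- character()
    sampleHap <- character()
    for (l in locs) {
      pool <- sample(pools[[l]])
      n <- config$samplesPerLocality
      if (length(pool) > n) {
        stop("locality pool exceeds samplesPerLocality; increase samples",
          call. = FALSE
        )
      }
      wts <- config$geomRatio^(seq_along(pool) - 1)
      extra <- sample(pool, n - length(pool),
        replace = TRUE, prob = wts / sum(wts)
      )
      draws <- c(pool, extra)
      ids <- paste0(l, sprintf("%04d", seq_len(n)))
      for (k in seq_len(n)) {
        sq <- hapSeq[[draws[k]]]
        if (config$missingRate > 0) {
          mask <- stats::runif(L) < config$missingRate
          sq[mask] <- "N"
        }
        seqs[ids[k]] <- paste(sq, collapse = "")
      }
      sampleLoc <- c(sampleLoc, setNames(rep(l, n), ids))
      sampleHap <- c(sampleHap, setNames(draws, ids))
    }

    meta <- data.frame(
      locality = unname(sampleLoc),
      country = unname(country[sampleLoc]),
      species = unname(speciesOf[sampleLoc]),
      row.names = names(sampleLoc), stringsAsFactors = FALSE
    )
    frame <- ReferenceFrame("NC_000934", 11750L, 11749L + L)
    aln <- MtAlignment(seqs, meta, frame = frame)

    keySitesDf <- do.call(rbind, keySites)
    ord <- order(keySitesDf$column)
    key <- new("DiagnosticKey",
      sites = keySitesDf[ord, , drop = FALSE],
      stateMaps = keyMaps[ord], hierarchy = hierarchy
    )
    truth <- list(
      subclade = setNames(unname(hapSub[sampleHap]), names(sampleHap)),
      locality = sampleLoc,
      haplotype = sampleHap,
      haplotypes = list(
        sequence = vapply(hapSeq, paste, character(1), collapse = ""),
        subclade = hapSub,
        localities = hapLocs
      ),
      key = key,
      hierarchy = hierarchy,
      homeSubclade = home,
      localityCountry = country
    )
    list(alignment = aln, truth = truth)
  })
}

#' Simulate nuclear (microsatellite-style) locality assignments
#'
#' Each sample is assigned its true locality with probability
#' `1 - nuclearMisassignmentRate`, otherwise a uniformly random other
#' locality, independent of mtDNA subclade — reproducing the mito-nuclear
#' discordance under which nuclear partitioning follows species boundaries
#' rather than mtDNA structure.
#'
#' @param config a `SimConfig`.
#' @param truth the `truth` component of [simulateMtdna()].
#' @param seed optional override (default `config$seed + 1` so the nuclear
#'   process is independent of the sequence draw).
#' @return data.frame of assignment records (`sample_id`, `true_locality`,
#'   `assigned_locality`, `species_group`).
#' @export
simulateNuclearAssignments <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(seed, {
    ids <- names(truth$locality)
    locs <- sort(unique(unname(truth$locality)))
    cladeOfSub <- setNames(
      rep(names(truth$hierarchy), lengths(truth$hierarchy)),
      unlist(truth$hierarchy, use.names = FALSE)
    )
    species <- ifelse(cladeOfSub[truth$homeSubclade[truth$locality]] == "F",
      "forest", "savanna"
    )
    assigned <- unname(truth$locality)
    flip <- stats::runif(length(ids)) < config$nuclearMisassignmentRate
    for (i in which(flip)) {
      assigned[i] <- sample(setdiff(locs, assigned[i]), 1L)
    }
    data.frame(
      sample_id = ids,
      true_locality = unname(truth$locality),
      assigned_locality = assigned,
      species_group = unname(species),
      stringsAsFactors = FALSE
    )
  })
}
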