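#' @include AllClasses.R AllGenerics.R utils.R
NULL

# state -> child maps for one column given a grouping of haplotypes.
# A state is *fixed* for child c when every haplotype of c carries it and no
# haplotype outside c does. A state is a *group-specific polymorphism* (voting
# state) when it is not the column's majority state and all of its carriers
# lie in a single child. Returns NULL when the column is uninformative.
.columnSiteMap <- function(states, group) {
  ok <- states != "N"
  if (!any(ok)) {
    return(NULL)
  }
  st <- states[ok]
  gr <- group[ok]
  tab <- table(st)
  children <- unique(group)
  fixedMap <- character()
  for (s in names(tab)) {
    inChild <- unique(gr[st == s])
    if (length(inChild) == 1L) {
      c0 <- inChild
      if (all(st[gr == c0] == s) && sum(gr == c0) == sum(group == c0)) {
        fixedMap[s] <- c0
      }
    }
  }
  if (length(fixedMap)) {
    return(list(map = fixedMap, fixed = TRUE))
  }
  top <- names(tab)[tab == max(tab)]
  majority <- if (length(top) == 1L) top else character()
  voteMap <- character()
  for (s in setdiff(names(tab), majority)) {
    inChild <- unique(gr[st == s])
    if (length(inChild) == 1L) voteMap[s] <- inChild
  }
  if (length(voteMap)) list(map = voteMap, fixed = FALSE) else NULL
}

#' Derive a hierarchical diagnostic-site key from labeled haplotypes
#'
#' Scans the variable columns of a labeled haplotype table for diagnostic
#' sites at two levels. A clade-level site is a column whose states partition
#' the clades with no exception (every observed state confined to one clade);
#' these are emitted with `fixed = TRUE`. Within each clade, a column is
#' fixed for a subclade when a state is carried by all of that subclade's
#' haplotypes and by no other haplotype of the clade ("fixed by subclade").
#' Columns that are merely group-specific polymorphisms — a non-majority
#' state whose carriers all belong to one group, but with within-group
#' exceptions — are emitted with `fixed = FALSE` and contribute only votes
#' during classification, never conflicts.
#'
#' @param table a [HaplotypeTable-class] of training haplotypes.
#' @param labels named character vector mapping every haplotype id of
#'   `table` to its subclade label.
#' @param hierarchy named list mapping each clade label to the character
#'   vector of its subclades, e.g.
#'   `list(F = c("western", ...), S = c("savanna-wide", ...))`.
#' @return A [DiagnosticKey-class].
#' @export
deriveDiagnosticKey <- function(table, labels, hierarchy) {
  stopifnot(is(table, "HaplotypeTable"), is.list(hierarchy))
  hapIds <- names(table@sequences)
  if (!all(hapIds %in% names(labels))) {
    stop("every training haplotype must be labeled; missing: ",
      paste(setdiff(hapIds, names(labels)), collapse = ", "),
      call. = FALSE
    )
  }
  subLab <- unname(labels[hapIds])
  allSubs <- unlist(hierarchy, use.names = FALSE)
  if (!all(subLab %in% allSubs)) {
    stop("labels outside the declared hierarchy: ",
      paste(setdiff(subLab, allSubs), collapse = ", "),
      call. = FALSE
    )
  }
  empty <- setdiff(allSubs, subLab)
  if (length(empty)) {
    stop("no training haplotype for subclade(s): ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  cladeOf <- setNames(
    rep(names(hierarchy), lengths(hierarchy)),
    unlist(hierarchy, use.names = FALSE)
  )
  cladeLab <- unname(cladeOf[subLab])

  m <- .seqMatrix(table@sequences)
  vs <- table@variableSites
  sites <- list()
  maps <- list()
  addSite <- function(col, level, parent, res) {
    sites[[length(sites) + 1L]] <<- data.frame(
      column = col, refPosition = table@frame@columnToRef[col],
      level = level, parent = parent, fixed = res$fixed,
      stringsAsFactors = FALSE
    )
    maps[[length(maps) + 1L]] <<- res$map
  }
  for (col in vs) {
    res <- .columnSiteMap(m[, col], cladeLab)
    if (!is.null(res)) addSite(col, "clade", "root", res)
  }
  for (cl in names(hierarchy)) {
    inClade <- cladeLab == cl
    if (sum(inClade) < 2L || length(hierarchy[[cl]]) < 2L) next
    for (col in vs) {
      res <- .columnSiteMap(m[inClade, col], subLab[inClade])
      if (!is.null(res)) addSite(col, "subclade", cl, res)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(
      column = integer(), refPosition = integer(), level = character(),
      parent = character(), fixed = logical()
    )
  new("DiagnosticKey", sites = sites, stateMaps = maps, hierarchy = hierarchy)
}

# core decision procedure over one sequence's states at the key's sites.
# siteStates: character vector parallel to key@sites rows (NA = missing).
.classifyStates <- function(key, siteStates) {
  s <- key@sites
  votes <- integer()
  nEval <- 0L
  nMiss <- 0L
  tally <- function(idx) {
    v <- character()
    for (i in idx) {
      st <- siteStates[i]
      if (is.na(st) || st == "N") {
        nMiss <<- nMiss + 1L
        next
      }
      lab <- key@stateMaps[[i]][st]
      if (is.na(lab)) next # state carries no signal at this site
      nEval <<- nEval + 1L
      v <- c(v, unname(lab))
    }
    v
  }
  # clade step: majority over non-missing fixed clade sites; tie or nothing
  # usable -> unassigned, stop
  cladeIdx <- which(s$level == "clade" & s$fixed)
  cv <- tally(cladeIdx)
  out <- list(
    clade = "unassigned", subclade = "unassigned",
    nSitesEvaluated = 0L, nSitesMissing = 0L, votes = table(character())
  )
  if (!length(cv)) {
    out$nSitesEvaluated <- nEval
    out$nSitesMissing <- nMiss
    return(out)
  }
  tb <- table(cv)
  top <- names(tb)[tb == max(tb)]
  if (length(top) != 1L) {
    out$nSitesEvaluated <- nEval
    out$nSitesMissing <- nMiss
    return(out)
  }
  clade <- top
  out$clade <- clade
  # subclade step within the assigned clade: fixed sites decide; if they
  # disagree -> conflict; none usable -> strict plurality over voting sites
  fixIdx <- which(s$level == "subclade" & s$parent == clade & s$fixed)
  fv <- tally(fixIdx)
  if (length(fv)) {
    u <- unique(fv)
    out$subclade <- if (length(u) == 1L) u else "conflict"
  } else {
    voteIdx <- which(s$level == "subclade" & s$parent == clade & !s$fixed)
    vv <- tally(voteIdx)
    if (length(vv)) {
      tb2 <- table(vv)
      top2 <- names(tb2)[tb2 == max(tb2)]
      if (length(top2) == 1L) out$subclade <- top2
      out$votes <- tb2
    } else if (length(hierarchy <- key@hierarchy[[clade]]) == 1L) {
      # degenerate hierarchy: single subclade needs no subclade-level site
      out$subclade <- hierarchy
    }
  }
  out$nSitesEvaluated <- nEval
  out$nSitesMissing <- nMiss
  out
}

#' Classify one sequence with a diagnostic key
#'
#' Evaluates clade-level fixed sites first (majority rule over the
#' non-missing ones; ties or no usable site leave the sequence unassigned),
#' then the subclade-level sites of the assigned clade: agreeing fixed sites
#' assign the subclade, contradictory fixed sites declare a `conflict`, and
#' when no fixed site is usable a strict plurality over the voting
#' (`fixed = FALSE`) sites is required. All failure modes are assignment
#' states, never errors, so partial sequences degrade to `unassigned`.
#'
#' @param sequence a character string over the key's coordinate frame.
#' @param key a [DiagnosticKey-class].
#' @param columns optional integer vector (parallel to the key's sites)
#'   translating each site to a column of `sequence`; defaults to the key's
#'   own columns. `NA` marks sites outside the sequenced window.
#' @return A list with elements `clade`, `subclade`, `nSitesEvaluated`,
#'   `nSitesMissing`, `votes`.
#' @export
classifySequence <- function(sequence, key, columns = NULL) {
  stopifnot(is(key, "DiagnosticKey"))
  if (is.null(columns)) columns <- key@sites$column
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  st <- rep(NA_character_, length(columns))
  ok <- !is.na(columns) & columns >= 1L & columns <= length(ch)
  st[ok] <- ch[columns[ok]]
  .classifyStates(key, st)
}

#' Classify every sample of a dataset
#'
#' Applies [classifySequence()] to each sample, translating the key's site
#' coordinates into the dataset's alignment columns through reference
#' positions (sites falling outside the dataset's window count as missing).
#' Also reports the per-locality subclade frequency table and flags samples
#' whose species label contradicts their clade assignment (forest-species
#' samples carrying S clade mtDNA — a pattern absent from reference data,
#' where S clade occurs only in savanna and hybrid individuals).
#'
#' @param x an [MtAlignment-class].
#' @param key a [DiagnosticKey-class].
#' @return A list: `assignments` (data.frame with `sample_id`, `clade`,
#'   `subclade`, `n_sites_evaluated`, `n_sites_missing`), `summary`
#'   (locality x subclade count table), `speciesCladeFlags` (sample ids of
#'   forest-species samples assigned to the S clade).
#' @export
classifyDataset <- function(x, key) {
  stopifnot(is(x, "MtAlignment"), is(key, "DiagnosticKey"))
  ids <- sampleIds(x)
  if (!length(ids)) {
    return(list(
      assignments = data.frame(
        sample_id = character(), clade = character(), subclade = character(),
        n_sites_evaluated = integer(), n_sites_missing = integer()
      ),
      summary = table(character(), character()),
      speciesCladeFlags = character()
    ))
  }
  cols <- .refToColumn(x@frame, key@sites$refPosition)
  m <- .seqMatrix(x)
  res <- lapply(seq_along(ids), function(i) {
    st <- rep(NA_character_, length(cols))
    ok <- !is.na(cols)
    st[ok] <- m[i, cols[ok]]
    .classifyStates(key, st)
  })
  assignments <- data.frame(
    sample_id = ids,
    clade = vapply(res, `[[`, character(1), "clade"),
    subclade = vapply(res, `[[`, character(1), "subclade"),
    n_sites_evaluated = vapply(res, `[[`, integer(1), "nSitesEvaluated"),
    n_sites_missing = vapply(res, `[[`, integer(1), "nSitesMissing"),
    stringsAsFactors = FALSE
  )
  meta <- as.data.frame(x@sampleData)
  summary <- table(locality = meta$locality, subclade = assignments$subclade)
  flags <- ids[meta$species == "forest" & assignments$clade == "S"]
  list(assignments = assignments, summary = summary, speciesCladeFlags = flags)
}

#' Write a diagnostic key to JSON or TSV
#'
#' JSON round-trips exactly through [readDiagnosticKey()]; the TSV form
#' serializes each site's state map as `state>label` pairs separated by `;`.
#'
#' @param key a [DiagnosticKey-class].
#' @param path output path.
#' @param format `"json"` or `"tsv"`; default guessed from the extension.
#' @return Invisibly, `key`.
#' @export
writeDiagnosticKey <- function(key, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  format <- match.arg(format, c("json", "tsv"))
  if (format == "json") {
    obj <- list(
      hierarchy = key@hierarchy,
      sites = lapply(seq_len(nrow(key@sites)), function(i) {
        c(
          as.list(key@sites[i, , drop = FALSE]),
          list(state_map = as.list(key@stateMaps[[i]]))
        )
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    sm <- vapply(key@stateMaps, function(mp) {
      paste(paste0(names(mp), ">", unname(mp)), collapse = ";")
    }, character(1))
    df <- cbind(key@sites, state_map = sm)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(key)
}

#' Read a diagnostic key written by [writeDiagnosticKey()]
#'
#' @param path path to a JSON or TSV key file.
#' @param format `"json"` or `"tsv"`; default guessed from the extension.
#' @return A [DiagnosticKey-class].
#' @export
readDiagnosticKey <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  format <- match.arg(format, c("json", "tsv"))
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    sites <- do.call(rbind, lapply(obj$sites, function(s) {
      data.frame(
        column = as.integer(s$column), refPosition = as.integer(s$refPosition),
        level = s$level, parent = s$parent, fixed = as.logical(s$fixed),
        stringsAsFactors = FALSE
      )
    }))
    maps <- lapply(obj$sites, function(s) {
      unlist(lapply(s$state_map, as.character))
    })
    hierarchy <- lapply(obj$hierarchy, function(v) unlist(lapply(v, as.character)))
  } else {
    df <- utils::read.delim(path, sep = "\t", colClasses = "character")
    sites <- data.frame(
      column = as.integer(df$column), refPosition = as.integer(df$refPosition),
      level = df$level, parent = df$parent, fixed = as.logical(df$fixed),
      stringsAsFactors = FALSE
    )
    maps <- lapply(df$state_map, function(s) {
      pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ">", fixed = TRUE)
      setNames(
        vapply(pairs, `[`, character(1), 2),
        vapply(pairs, `[`, character(1), 1)
      )
    })
    subs <- unique(sites$parent[sites$level == "subclade"])
    hierarchy <- lapply(setNames(subs, subs), function(cl) {
      unique(unlist(maps[sites$level == "subclade" & sites$parent == cl]))
    })
  }
  new("DiagnosticKey", sites = sites, stateMaps = maps, hierarchy = hierarchy)
}

setMethod("show", "DiagnosticKey", function(object) {
  s <- object@sites
  cat(sprintf(
    "DiagnosticKey: %d site(s) (%d clade-level, %d subclade-level; %d fixed)\n",
    nrow(s), sum(s$level == "clade"), sum(s$level == "subclade"), sum(s$fixed)
  ))
  for (cl in names(object@hierarchy)) {
    cat(sprintf(
      "  %s -> %s\n", cl,
      paste(object@hierarchy[[cl]], collapse = ", ")
    ))
  }
})
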