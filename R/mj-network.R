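#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Hamming distances between rows of a character matrix (variable sites only).
# Counted as L minus matches, accumulated per state via tcrossprod so the
# work happens in BLAS rather than interpreted loops.
.rowHamming <- function(m) {
  n <- nrow(m)
  if (n < 2 || !ncol(m)) {
    return(matrix(0, max(n, 0), max(n, 0)))
  }
  matches <- matrix(0, n, n)
  for (s in unique(as.vector(m))) {
    matches <- matches + tcrossprod((m == s) * 1)
  }
  ncol(m) - matches
}

# epsilon-relaxed minimum spanning network: edge (i,j) of weight w is kept
# iff i and j are not connected using only edges of weight < w - epsilon.
# With epsilon = 0 this is the classical MSN (union of all MSTs).
.msnEdges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n < 2) {
    return(matrix(integer(), ncol = 3, dimnames = list(NULL, c("i", "j", "w"))))
  }
  ut <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[ut]
  ord <- order(w, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  w <- w[ord]
  keep <- logical(length(w))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  uw <- unique(w)
  if (epsilon == 0L) {
    # incremental: when weight class wv is examined, the union-find holds
    # exactly the edges of weight < wv
    for (wv in uw) {
      cls <- which(w == wv)
      for (e in cls) {
        if (find(ut[e, 1]) != find(ut[e, 2])) keep[e] <- TRUE
      }
      for (e in cls) {
        a <- find(ut[e, 1])
        b <- find(ut[e, 2])
        if (a != b) parent[a] <- b
      }
    }
  } else {
    for (wv in uw) {
      parent <- seq_len(n)
      for (e in which(w < wv - epsilon)) {
        a <- find(ut[e, 1])
        b <- find(ut[e, 2])
        if (a != b) parent[a] <- b
      }
      for (e in which(w == wv)) {
        if (find(ut[e, 1]) != find(ut[e, 2])) keep[e] <- TRUE
      }
    }
  }
  cbind(i = ut[keep, 1], j = ut[keep, 2], w = w[keep])
}

.mstCost <- function(D) {
  n <- nrow(D)
  if (n < 2) {
    return(0)
  }
  # Prim's algorithm on the complete distance graph
  inTree <- logical(n)
  inTree[1] <- TRUE
  best <- D[, 1]
  cost <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!inTree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    inTree[v] <- TRUE
    best <- pmin(best, D[, v])
  }
  as.numeric(cost)
}

# candidate median sequences for a mutually connected triple. Majority state
# per column; at three-way ties each parental state is kept, yielding up to
# three candidates (all tied columns resolved toward the same parent).
.tripleMedians <- function(a, b, c) {
  med <- a # covers majorities a==b, a==c, and tie->a
  bc <- b == c
  med[bc] <- b[bc] # majority b==c
  tie <- !bc & a != b & a != c
  if (!any(tie)) {
    return(list(med))
  }
  m2 <- med
  m2[tie] <- b[tie]
  m3 <- med
  m3[tie] <- c[tie]
  list(med, m2, m3)
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining algorithm over the haplotypes' variable
#' sites: (1) pairwise Hamming distances; (2) the epsilon-relaxed minimum
#' spanning network (all links within `epsilon` of the minimal connection
#' cost are kept, so the classical MSN at `epsilon = 0`); (3) for every
#' feasible triple — two links sharing a node, which covers mutually
#' connected triples through their cheapest center — candidate median
#' vectors (per-column majority; three-way ties keep each parental state);
#' (4) medians whose star connection cost is lower than the cost of the
#' triple's two existing links are added as frequency-0 nodes — per pass,
#' only candidates within `epsilon` of the best improvement; (5) repeat
#' until no median is added; (6) obsolete medians (whose removal leaves the
#' node set connectable at equal spanning cost) are pruned. The result is
#' deterministic given the haplotype ordering of [collapseHaplotypes()].
#'
#' @param table a [HaplotypeTable-class]; haplotype representatives must be
#'   free of `N` at variable sites (exclude such samples upstream with the
#'   `strict`/`resolve` collapsing policies).
#' @param epsilon non-negative integer tolerance; 0 is the conventional
#'   default.
#' @param maxIter safety cap on median-addition passes.
#' @return A [HaplotypeNetwork-class]; its graph holds vertex attributes
#'   `name`, `kind` ("observed"/"median"), `frequency`, `sequence` (over
#'   variable sites), `localities`, and edge attribute `weight`.
#' @export
buildMJNetwork <- function(table, epsilon = 0L, maxIter = 100L) {
  stopifnot(is(table, "HaplotypeTable"))
  epsilon <- as.integer(epsilon)
  if (epsilon < 0L) stop("epsilon must be >= 0", call. = FALSE)
  vs <- table@variableSites
  m <- .seqMatrix(table@sequences)[, vs, drop = FALSE]
  if (any(m == "N")) {
    bad <- names(table@sequences)[rowSums(m == "N") > 0]
    stop(
      "haplotype(s) with N at variable sites: ", paste(bad, collapse = ", "),
      "; exclude them upstream (collapse with policy 'strict' or 'resolve')",
      call. = FALSE
    )
  }
  nObs <- nrow(m)
  nodes <- m
  rownames(nodes) <- names(table@sequences)
  nMedian <- 0L

  for (iter in seq_len(maxIter)) {
    D <- .rowHamming(nodes)
    edges <- .msnEdges(D, epsilon)
    if (!nrow(edges)) break
    # feasible triples: two links sharing a node (u - v - w through center
    # v); mutually connected triples are covered through their best center
    nn <- nrow(nodes)
    adj <- matrix(FALSE, nn, nn)
    adj[edges[, c("i", "j"), drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    tri <- do.call(cbind, lapply(seq_len(nn), function(v) {
      nb <- which(adj[v, ])
      if (length(nb) < 2) {
        return(matrix(integer(), nrow = 3))
      }
      pr <- utils::combn(nb, 2L)
      rbind(pr[1, ], v, pr[2, ])
    }))
    if (!length(tri)) break
    # screen triples that cannot yield an improving median: any median x
    # satisfies 2 cost(x) >= perimeter S (triangle inequality), so a triple
    # is only worth evaluating when ceil(S/2) beats the cost of its two
    # existing links
    du <- D[cbind(tri[1, ], tri[2, ])]
    dv <- D[cbind(tri[1, ], tri[3, ])]
    dw <- D[cbind(tri[2, ], tri[3, ])]
    S <- du + dv + dw
    current <- du + dw # the two links through the center
    open <- which(ceiling(S / 2) + epsilon < current)
    existing <- new.env(hash = TRUE, parent = emptyenv())
    for (s in .collapseRows(nodes)) assign(s, TRUE, envir = existing)
    # candidate registry deduplicated at insertion (keyed on sequence,
    # keeping the lowest connection cost seen)
    reg <- new.env(hash = TRUE, parent = emptyenv())
    regSeq <- new.env(hash = TRUE, parent = emptyenv())
    for (t3 in open) {
      a <- nodes[tri[1, t3], ]
      b <- nodes[tri[2, t3], ]
      cc <- nodes[tri[3, t3], ]
      # medians only differ from a at columns where the triple disagrees
      idx <- which(a != b | a != cc)
      a2 <- a[idx]
      b2 <- b[idx]
      c2 <- cc[idx]
      for (x2 in .tripleMedians(a2, b2, c2)) {
        cost <- sum(x2 != a2) + sum(x2 != b2) + sum(x2 != c2)
        if (cost >= current[t3]) next
        x <- a
        x[idx] <- x2
        key <- paste(x, collapse = "")
        if (exists(key, envir = existing, inherits = FALSE)) next
        prev <- reg[[key]]
        if (is.null(prev) || cost < prev) {
          reg[[key]] <- cost
          if (is.null(prev)) regSeq[[key]] <- x
        }
      }
    }
    keys <- ls(reg)
    if (!length(keys)) break
    costs <- vapply(keys, function(k) reg[[k]], numeric(1))
    sel <- keys[costs <= min(costs) + epsilon]
    add <- do.call(rbind, lapply(sel, function(k) regSeq[[k]]))
    rownames(add) <- sprintf("mv%03d", nMedian + seq_len(nrow(add)))
    nMedian <- nMedian + nrow(add)
    nodes <- rbind(nodes, add)
  }

  # prune obsolete median vectors: those whose removal leaves the node set
  # connectable at equal spanning cost (low-degree medians first, latest
  # added first, for a deterministic order)
  repeat {
    D <- .rowHamming(nodes)
    edges <- .msnEdges(D, epsilon)
    deg <- tabulate(c(edges[, "i"], edges[, "j"]), nbins = nrow(nodes))
    base <- .mstCost(D)
    removed <- FALSE
    meds <- rev(seq_len(nrow(nodes)))
    meds <- meds[meds > nObs]
    for (k in meds[order(deg[meds])]) {
      if (.mstCost(D[-k, -k, drop = FALSE]) <= base) {
        nodes <- nodes[-k, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  D <- .rowHamming(nodes)
  edges <- .msnEdges(D, epsilon)
  kind <- c(rep("observed", nObs), rep("median", nrow(nodes) - nObs))
  freq <- c(rowSums(table@counts), rep(0L, nrow(nodes) - nObs))
  locStr <- vapply(seq_len(nrow(nodes)), function(k) {
    if (k > nObs) {
      return("")
    }
    cnt <- table@counts[k, ]
    cnt <- cnt[cnt > 0]
    paste(paste0(names(cnt), ":", cnt), collapse = ",")
  }, character(1))
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(nodes))
  g <- igraph::set_vertex_attr(g, "kind", value = kind)
  g <- igraph::set_vertex_attr(g, "frequency", value = as.numeric(freq))
  g <- igraph::set_vertex_attr(g, "sequence", value = .collapseRows(nodes))
  g <- igraph::set_vertex_attr(g, "localities", value = locStr)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges[, c("i", "j"), drop = FALSE]),
      weight = as.numeric(edges[, "w"])
    )
  }
  new("HaplotypeNetwork",
    graph = g, epsilon = epsilon,
    variableSites = as.integer(vs), cost = .mstCost(D)
  )
}

#' Check that subclade labels group contiguously on a network
#'
#' A sound subclade classification should place each subclade's haplotypes
#' in a connected patch of the network. Median (inferred) nodes are
#' attributed to the subclade of their nearest labeled observed node (graph
#' distance; deterministic tie-break by vertex order), then each subclade's
#' induced subgraph is tested for connectedness.
#'
#' @param network a [HaplotypeNetwork-class].
#' @param assignments named character vector: observed node name -> subclade
#'   label (must cover every observed node).
#' @return A list: `ok` (logical), `offenders` (character vector of node
#'   names lying outside their subclade's largest connected block; empty
#'   when `ok`).
#' @export
subcladeGroupingCheck <- function(network, assignments) {
  g <- network@graph
  kind <- igraph::vertex_attr(g, "kind")
  nm <- igraph::vertex_attr(g, "name")
  obs <- nm[kind == "observed"]
  missing <- setdiff(obs, names(assignments))
  if (length(missing)) {
    stop("unlabeled observed node(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  lab <- setNames(rep(NA_character_, length(nm)), nm)
  lab[obs] <- unname(assignments[obs])
  med <- nm[kind == "median"]
  if (length(med)) {
    dd <- igraph::distances(g, v = med, to = obs, weights = igraph::E(g)$weight)
    for (i in seq_along(med)) {
      lab[med[i]] <- unname(assignments[obs[which.min(dd[i, ])]])
    }
  }
  offenders <- character()
  for (s in unique(assignments)) {
    vset <- nm[lab == s]
    sub <- igraph::induced_subgraph(g, vset)
    comp <- igraph::components(sub)
    if (comp$no > 1L) {
      main <- which.max(comp$csize)
      offenders <- c(
        offenders,
        intersect(igraph::V(sub)$name[comp$membership != main], obs)
      )
    }
  }
  list(ok = length(offenders) == 0L, offenders = offenders)
}

#' Export a haplotype network to GML or DOT
#'
#' @param x a [HaplotypeNetwork-class].
#' @param path output file path.
#' @param format `"gml"` or `"dot"`; default guessed from the extension.
#' @return Invisibly, `x`.
#' @export
writeNetwork <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.dot$", path, ignore.case = TRUE)) "dot" else "gml"
  }
  format <- match.arg(format, c("gml", "dot"))
  igraph::write_graph(x@graph, path, format = format)
  invisible(x)
}

#' Accessors for HaplotypeNetwork
#'
#' @param x a [HaplotypeNetwork-class].
#' @return `networkGraph`: the underlying igraph; `networkCost`: the
#'   minimum-spanning cost over the final node set (total mutational steps).
#' @name HaplotypeNetwork-accessors
NULL

#' @rdname HaplotypeNetwork-accessors
#' @export
setMethod("networkGraph", "HaplotypeNetwork", function(x) x@graph)

#' @rdname HaplotypeNetwork-accessors
#' @export
setMethod("networkCost", "HaplotypeNetwork", function(x) x@cost)

setMethod("show", "HaplotypeNetwork", function(object) {
  g <- object@graph
  kind <- igraph::vertex_attr(g, "kind")
  cat(sprintf(
    "HaplotypeNetwork: %d observed + %d median node(s), %d edge(s), cost %g (epsilon %d)\n",
    sum(kind == "observed"), sum(kind == "median"),
    igraph::ecount(g), object@cost, object@epsilon
  ))
})
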