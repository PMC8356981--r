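# Graph construction: OMST topological filtering, data-driven multi-metric
# integration, and sparsity-matched thresholding / re-weighting.
#
# Throughout, edge weights encode connection strength, so the weight-to-
# distance transform for shortest paths and spanning trees is d = 1/w; a
# weight of zero means "no edge", never distance zero.

.igraphOf <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

.isConnected <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  igraph::is_connected(g)
}

#' Sparsity (edge density) of a connectome
#'
#' Fraction of the `n(n-1)/2` possible edges that are present.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return numeric in `[0, 1]`.
#' @export
sparsityOf <- function(x) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  sum(W[upper.tri(W)] > 0) / (nrow(W) * (nrow(W) - 1) / 2)
}

#' Normalise a connectome to a maximum edge weight of 1
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return object of the same kind with weights divided by their maximum
#'   (unchanged if the graph has no edges).
#' @export
maxNormalize <- function(x) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  mx <- max(W)
  if (mx > 0) W <- W / mx
  if (is(x, "Connectome")) Connectome(W, nodeLabels(x)) else W
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with edge
#' length `1/weight` (Rubinov & Sporns convention). Equals 1 for a complete
#' graph with unit weights and 0 for an edgeless graph (disconnected pairs
#' contribute 0).
#'
#' @param x a [Connectome-class] or weight matrix.
#' @return numeric efficiency in `[0, 1]` for max-normalised graphs.
#' @export
#' @examples
#' globalEfficiency(matrix(1, 4, 4) - diag(4))
globalEfficiency <- function(x) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  n <- nrow(W)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  if (all(W == 0)) return(0)
  g <- .igraphOf(W)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / D
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

# deterministic Kruskal minimum spanning tree on distance = 1/weight;
# ties broken lexicographically by (i, j). Returns an edge index matrix.
.kruskalMst <- function(W) {
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0)
  i <- row(W)[ut]; j <- col(W)[ut]; w <- W[ut]
  ord <- order(1 / w, i, j)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- integer(0)
  for (e in ord) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) {
      parent[ri] <- rj
      keep <- c(keep, e)
      if (length(keep) == n - 1) break
    }
  }
  cbind(i[keep], j[keep])
}

#' Orthogonal-MST topological filtering
#'
#' Iteratively extracts minimum spanning trees (on distance = 1/weight),
#' removing each tree's edges before the next round so successive trees are
#' edge-disjoint ("orthogonal"). After adding each tree, the global
#' cost-efficiency J = globalEfficiency(accumulated) - cost is evaluated,
#' where cost is the fraction of the input's total edge weight captured by the
#' accumulated edges. The accumulation with maximal J is returned; surviving
#' edges keep their original weights. The full J curve is returned so the
#' selection can be audited.
#'
#' @param x a connected [Connectome-class] or weight matrix.
#' @param maxTrees maximum number of orthogonal MSTs to consider (>= 1).
#' @return An [OmstResult-class].
#' @export
omstFilter <- function(x, maxTrees = 10) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  labels <- if (is(x, "Connectome")) nodeLabels(x) else NULL
  if (maxTrees < 1) stop("maxTrees must be >= 1")
  if (!.isConnected(W)) stop("OMST filtering requires a connected input graph")
  totalWeight <- sum(W) / 2
  remaining <- W
  acc <- matrix(0, nrow(W), ncol(W))
  curve <- data.frame(nTrees = integer(0), cost = numeric(0), J = numeric(0))
  candidates <- list()
  for (t in seq_len(maxTrees)) {
    if (!.isConnected(remaining)) break
    tree <- .kruskalMst(remaining)
    acc[tree] <- W[tree]
    acc[tree[, 2:1, drop = FALSE]] <- W[tree]
    remaining[tree] <- 0
    remaining[tree[, 2:1, drop = FALSE]] <- 0
    cost <- sum(acc) / 2 / totalWeight
    J <- globalEfficiency(acc) - cost
    curve <- rbind(curve, data.frame(nTrees = t, cost = cost, J = J))
    candidates[[t]] <- acc
  }
  best <- which.max(curve$J)
  filtered <- if (is.null(labels)) Connectome(candidates[[best]])
              else Connectome(candidates[[best]], labels)
  new("OmstResult", filtered = filtered, nTreesUsed = as.integer(best),
      costEfficiency = curve)
}

# min-max rescale the nonzero entries of a symmetric matrix to [0, 1]
.rescaleEdges <- function(M, mask) {
  v <- M[mask]
  r <- range(v)
  out <- matrix(0, nrow(M), ncol(M))
  out[mask] <- if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else 0.5
  out
}

#' Data-driven integration of several edge metrics
#'
#' Combines the selected metrics into a single edge-weight matrix that
#' down-weights mutually similar metrics and up-weights dissimilar ones. Each
#' metric is first min-max rescaled to `[0, 1]` over its nonzero entries (MD
#' and RD are additionally inverted, `1 - rescaled`, so "high = stronger
#' connection" semantics align across metrics). The combination is
#' `sum_m alpha_m * M_m` with `alpha_m` proportional to the mean pairwise
#' dissimilarity of metric m to the other selected metrics, where
#' dissimilarity = 1 - |Pearson correlation| over the shared nonzero edges,
#' and the alphas normalised to sum to 1.
#'
#' @param stack a [MetricStack-class].
#' @param metricSubset character vector of at least two metric names.
#' @return A [Connectome-class] with the integrated weights and an
#'   `"alpha"` attribute on its weight matrix recording the mixing weights.
#' @export
integrateMetrics <- function(stack, metricSubset = metricNames()) {
  stopifnot(is(stack, "MetricStack"))
  metricSubset <- unique(metricSubset)
  if (length(metricSubset) < 2)
    stop("metric integration needs at least 2 metrics")
  bad <- setdiff(metricSubset, metricNames())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  mask <- upper.tri(stack@metrics[["NS"]]) & stack@metrics[["NS"]] > 0
  resc <- lapply(metricSubset, function(m) {
    R <- .rescaleEdges(stack@metrics[[m]], mask)
    if (m %in% c("MD", "RD")) R[mask] <- 1 - R[mask]
    R
  })
  names(resc) <- metricSubset
  vecs <- vapply(resc, function(R) R[mask], numeric(sum(mask)))
  k <- length(metricSubset)
  C <- matrix(1, k, k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (sd(vecs[, a]) == 0 || sd(vecs[, b]) == 0) {
      warning("metric with zero variance over edges; correlation set to 0")
      C[a, b] <- C[b, a] <- 0
    } else {
      C[a, b] <- C[b, a] <- abs(cor(vecs[, a], vecs[, b]))
    }
  }
  dissim <- vapply(seq_len(k), function(a) mean(1 - C[a, -a]), numeric(1))
  alpha <- if (sum(dissim) > 0) dissim / sum(dissim) else rep(1 / k, k)
  names(alpha) <- metricSubset
  out <- Reduce(`+`, Map(function(R, a) a * R, resc, alpha))
  out <- out + t(out)
  attr(out, "alpha") <- alpha
  Connectome(out, nodeLabels(stack))
}

#' Threshold a connectome to a target sparsity
#'
#' Keeps the `ceiling(targetSparsity * n(n-1)/2)` highest-weight edges. Ties
#' at the cutoff are broken deterministically by keeping the lexicographically
#' smallest (i, j) pairs.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @param targetSparsity desired edge density in `(0, 1]`.
#' @return A [Connectome-class] (or matrix, matching the input kind).
#' @export
thresholdToSparsity <- function(x, targetSparsity) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  stopifnot(targetSparsity > 0, targetSparsity <= 1)
  n <- nrow(W)
  nKeep <- ceiling(targetSparsity * n * (n - 1) / 2)
  ut <- which(upper.tri(W) & W > 0)
  if (length(ut) < nKeep)
    stop(sprintf("cannot reach sparsity %.4f: %d nonzero edges available, %d needed",
                 targetSparsity, length(ut), nKeep))
  i <- row(W)[ut]; j <- col(W)[ut]
  keep <- ut[order(-W[ut], i, j)][seq_len(nKeep)]
  out <- matrix(0, n, n)
  out[keep] <- W[keep]
  out <- out + t(out)
  if (is(x, "Connectome")) Connectome(out, nodeLabels(x)) else out
}

.SCHEME_TABLE <- data.frame(
  symbol = LETTERS[1:7],
  id = c("NS-OMST", "NS+FA-OMST", "9m-OMST", "NS-thr",
         "NS-t/FA-w", "NS-t/MD-w", "FA-t/NS-w"),
  stringsAsFactors = FALSE)

#' Graph-construction scheme identifiers
#'
#' The seven supported schemes: three OMST-filtered (NS alone, NS+FA
#' integrated, all nine metrics integrated) and four sparsity-matched
#' thresholding schemes (threshold on NS or FA, optionally re-weighted by FA,
#' MD or NS). Both the symbolic letters A-G and the descriptive ids are
#' accepted wherever a scheme is named.
#'
#' @return data.frame with columns `symbol` and `id`.
#' @export
#' @examples
#' schemeIds()
schemeIds <- function() .SCHEME_TABLE

.resolveScheme <- function(scheme) {
  tab <- .SCHEME_TABLE
  hit <- match(toupper(scheme), tab$symbol)
  if (is.na(hit)) hit <- match(scheme, tab$id)
  if (is.na(hit)) stop("unknown graph-construction scheme: ", scheme)
  tab$id[hit]
}

# re-weight the surviving topology of `topo` with metric matrix M
.reweight <- function(topo, M) {
  W <- edgeWeights(topo)
  out <- ifelse(W > 0, M, 0)
  Connectome(out, nodeLabels(topo))
}

#' Apply a graph-construction scheme to a metric stack
#'
#' Builds one subject-session connectome under one of the seven schemes (see
#' [schemeIds()]). The thresholded schemes are sparsity-matched: their edge
#' count equals `referenceSparsity`, which defaults to `"auto"` — the sparsity
#' of the nine-metric OMST scheme (C) computed on the same stack. All outputs
#' are max-normalised to 1 with a zero diagonal.
#'
#' @param scheme scheme symbol ("A".."G") or id (e.g. "9m-OMST").
#' @param stack a [MetricStack-class].
#' @param referenceSparsity numeric in `(0, 1]`, or `"auto"`.
#' @param maxTrees forwarded to [omstFilter()].
#' @return A [Connectome-class].
#' @export
applyScheme <- function(scheme, stack, referenceSparsity = "auto",
                        maxTrees = 10) {
  stopifnot(is(stack, "MetricStack"))
  id <- .resolveScheme(scheme)
  NS <- Connectome(stack@metrics[["NS"]], nodeLabels(stack))
  out <- switch(
    id,
    "NS-OMST" = omstFilter(NS, maxTrees)@filtered,
    "NS+FA-OMST" = omstFilter(integrateMetrics(stack, c("NS", "FA")),
                              maxTrees)@filtered,
    "9m-OMST" = omstFilter(integrateMetrics(stack, metricNames()),
                           maxTrees)@filtered,
    {
      s <- if (identical(referenceSparsity, "auto"))
        sparsityOf(omstFilter(integrateMetrics(stack, metricNames()),
                              maxTrees)@filtered)
      else as.numeric(referenceSparsity)
      switch(id,
             "NS-thr" = thresholdToSparsity(NS, s),
             "NS-t/FA-w" = .reweight(thresholdToSparsity(NS, s),
                                     stack@metrics[["FA"]]),
             "NS-t/MD-w" = .reweight(thresholdToSparsity(NS, s),
                                     stack@metrics[["MD"]]),
             "FA-t/NS-w" = .reweight(
               thresholdToSparsity(Connectome(stack@metrics[["FA"]],
                                              nodeLabels(stack)), s),
               stack@metrics[["NS"]]))
    })
  maxNormalize(out)
}
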