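# Synthetic test-retest cohorts with planted modular ground truth.
#
# The generator emulates the statistical structure the repeatability analysis
# assumes: symmetric, non-negative, connected weighted graphs with modular
# organisation; a stack of nine correlated edge metrics per graph; and a
# second "scan" obtained from the first by controllable multiplicative weight
# noise and degree-preserving rewiring.

.seedGuard <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# deterministic sub-seed derivation, kept inside 32-bit range
.subSeed <- function(seed, ...) {
  ks <- c(...)
  x <- as.double(seed %% 2147483647)
  for (k in ks) x <- (x * 48271 + as.double(k)) %% 2147483647
  as.integer(x)
}

#' Generate a planted-partition weighted graph
#'
#' Draws a weighted undirected graph with known modular ground truth: node
#' pairs inside a module are connected with probability `pIn`, pairs in
#' different modules with probability `pOut`, and edge weights are uniform on
#' `[weightLow, weightHigh]`. If the realised graph is disconnected, the
#' lightest possible repair is applied: one edge of weight `weightLow` between
#' the smallest-indexed nodes of successive components, so the planted
#' densities are minimally disturbed.
#'
#' @param nNodes total number of nodes.
#' @param moduleSizes integer vector of module sizes; must sum to `nNodes`.
#' @param pIn within-module edge probability (must exceed `pOut`).
#' @param pOut between-module edge probability.
#' @param weightLow,weightHigh uniform edge-weight range.
#' @param seed integer RNG seed.
#' @return list with elements `graph` ([Connectome-class]) and `partition`
#'   ([HardPartition-class], the planted ground truth).
#' @export
#' @examples
#' g <- plantedPartitionGraph(40, rep(10, 4), pIn = 0.8, pOut = 0.05, seed = 1)
#' g$graph
plantedPartitionGraph <- function(nNodes, moduleSizes, pIn, pOut,
                                  weightLow = 0.5, weightHigh = 1, seed = 1) {
  if (sum(moduleSizes) != nNodes)
    stop("moduleSizes must sum to nNodes (got ", sum(moduleSizes), " vs ", nNodes, ")")
  if (any(moduleSizes < 1)) stop("module sizes must be positive")
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  if (weightLow <= 0 || weightHigh < weightLow)
    stop("need 0 < weightLow <= weightHigh")
  .seedGuard(seed)
  labels <- rep(seq_along(moduleSizes), moduleSizes)
  W <- matrix(0, nNodes, nNodes)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  same <- labels[ut[, 1]] == labels[ut[, 2]]
  p <- ifelse(same, pIn, pOut)
  on <- runif(nrow(ut)) < p
  w <- numeric(nrow(ut))
  w[on] <- runif(sum(on), weightLow, weightHigh)
  W[ut] <- w
  W <- W + t(W)
  W <- .repairConnectivity(W, weightLow)
  list(graph = Connectome(W),
       partition = HardPartition(labels, algorithm = "planted"))
}

# connect components with weight-`wlow` edges between their smallest nodes
.repairConnectivity <- function(W, wlow) {
  comp <- .componentsOf(W)
  while (max(comp) > 1) {
    a <- min(which(comp == 1))
    b <- min(which(comp == 2))
    W[a, b] <- W[b, a] <- wlow
    comp <- .componentsOf(W)
  }
  W
}

.componentsOf <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  igraph::components(g)$membership
}

.rescale01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Generate a nine-metric stack correlated with a base graph
#'
#' Builds the nine edge metrics carried by a [MetricStack-class] on the zero
#' pattern of `base`. `NS` equals the base matrix. Every other metric is a
#' standardised mixture `rho * base + sqrt(1 - rho^2) * noise` over the edge
#' values, mapped back to a positive range, so its Pearson correlation with
#' the base over edges is approximately `similarityProfile[m]` in magnitude.
#' `MD` and `RD` are generated on an inverted scale (large where the base is
#' small), mimicking diffusivity semantics, so their signed correlation with
#' the base is approximately minus the profile value. `ED` is the pairwise
#' Euclidean distance between random 3-D node coordinates (or `coords` if
#' supplied), restricted to the base's edges.
#'
#' @param base a [Connectome-class]; its weights play the role of NS.
#' @param similarityProfile named numeric vector in `[0, 1]` for the metrics
#'   other than NS (and ED, which is geometric); defaults chosen to mimic
#'   typical inter-metric correlations of white-matter edge weights.
#' @param seed integer RNG seed.
#' @param coords optional nNodes x 3 matrix of node coordinates for ED.
#' @return A [MetricStack-class].
#' @export
generateMetricStack <- function(base,
                                similarityProfile = c(FA = 0.7, MD = 0.6,
                                                      RD = 0.6, PS = 0.9,
                                                      SLD = 0.8, TV = 0.7,
                                                      TL = 0.5),
                                seed = 1, coords = NULL) {
  stopifnot(is(base, "Connectome"))
  needed <- setdiff(metricNames(), c("NS", "ED"))
  if (!all(needed %in% names(similarityProfile)))
    stop("similarityProfile is missing metric(s): ",
         paste(setdiff(needed, names(similarityProfile)), collapse = ", "))
  if (any(similarityProfile < 0 | similarityProfile > 1))
    stop("similarityProfile values must lie in [0, 1]")
  .seedGuard(seed)
  W <- edgeWeights(base)
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0)
  b <- W[ut]
  bstd <- if (sd(b) > 0) (b - mean(b)) / sd(b) else rep(0, length(b))

  mkMetric <- function(rho, invert = FALSE) {
    z <- rho * bstd + sqrt(max(0, 1 - rho^2)) * rnorm(length(b))
    if (invert) z <- -z
    v <- .rescale01(z) * 0.9 + 0.1  # keep weights strictly positive
    M <- matrix(0, n, n)
    M[ut] <- v
    M + t(M)
  }

  if (is.null(coords)) coords <- matrix(runif(3 * n, 0, 100), n, 3)
  D <- as.matrix(dist(coords))
  ED <- matrix(0, n, n)
  ED[ut] <- D[ut]
  ED <- ED + t(ED)

  metrics <- list(
    NS  = W,
    FA  = mkMetric(similarityProfile[["FA"]]),
    MD  = mkMetric(similarityProfile[["MD"]], invert = TRUE),
    RD  = mkMetric(similarityProfile[["RD"]], invert = TRUE),
    PS  = mkMetric(similarityProfile[["PS"]]),
    SLD = mkMetric(similarityProfile[["SLD"]]),
    TV  = mkMetric(similarityProfile[["TV"]]),
    TL  = mkMetric(similarityProfile[["TL"]]),
    ED  = ED)
  MetricStack(metrics, nodeLabels(base))
}

#' Session-noise specification for a test-retest cohort
#'
#' @param weightNoiseSd non-negative sd of multiplicative log-normal noise
#'   applied to session-2 edge weights (noise on the log scale keeps weights
#'   positive).
#' @param rewireFraction fraction of edges randomly rewired in session 2 via
#'   degree-preserving double-edge swaps (edge count preserved).
#' @return list of class "sessionNoiseSpec".
#' @export
sessionNoiseSpec <- function(weightNoiseSd = 0, rewireFraction = 0) {
  stopifnot(weightNoiseSd >= 0, rewireFraction >= 0, rewireFraction <= 1)
  structure(list(weightNoiseSd = weightNoiseSd,
                 rewireFraction = rewireFraction),
            class = "sessionNoiseSpec")
}

# apply session noise to one graph: degree-preserving rewiring of a fraction
# of edges, then multiplicative log-normal weight noise
.applySessionNoise <- function(W, noise) {
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0)
  m <- length(ut)
  edges <- cbind(row(W)[ut], col(W)[ut])
  weightsVec <- W[ut]
  if (noise$rewireFraction > 0 && m >= 2) {
    nAttempts <- ceiling(noise$rewireFraction * m / 2)
    edges2 <- .rewireConnected(edges, n, as.integer(nAttempts))
    W2 <- matrix(0, n, n)
    W2[edges2] <- weightsVec
    W2 <- W2 + t(W2)
    W <- W2
    ut <- which(upper.tri(W) & W > 0)
    weightsVec <- W[ut]
  }
  if (noise$weightNoiseSd > 0) {
    weightsVec <- weightsVec * exp(rnorm(length(ut), 0, noise$weightNoiseSd))
    W[upper.tri(W)] <- 0
    W[ut] <- weightsVec
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
  }
  W
}

#' Generate a synthetic test-retest cohort
#'
#' For each subject, session 1 is a fresh planted-partition graph; session 2
#' is session 1 with the session noise applied (degree-preserving rewiring of
#' a fraction of edges, then multiplicative log-normal weight noise). The
#' planted partition is recorded as ground truth. Fully reproducible from
#' `seed`.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param nNodes,moduleSizes,pIn,pOut,weightLow,weightHigh forwarded to
#'   [plantedPartitionGraph()].
#' @param noise a [sessionNoiseSpec()].
#' @param seed master integer seed.
#' @param withStacks logical; also generate nine-metric stacks per
#'   subject-session (session 2 reuses the subject's node coordinates for ED).
#' @param similarityProfile forwarded to [generateMetricStack()].
#' @return A [Cohort-class].
#' @export
#' @examples
#' coh <- testRetestCohort(4, nNodes = 20, moduleSizes = rep(5, 4), seed = 7)
#' coh
testRetestCohort <- function(nSubjects, nNodes = 40, moduleSizes = rep(10, 4),
                             pIn = 0.8, pOut = 0.05,
                             weightLow = 0.5, weightHigh = 1,
                             noise = sessionNoiseSpec(), seed = 1,
                             withStacks = FALSE,
                             similarityProfile = NULL) {
  if (nSubjects < 2) stop("need at least 2 subjects")
  subjects <- sprintf("sub%03d", seq_len(nSubjects))
  graphs <- list(); stacks <- list(); gt <- list()
  for (k in seq_len(nSubjects)) {
    s <- subjects[k]
    pg <- plantedPartitionGraph(nNodes, moduleSizes, pIn, pOut,
                                weightLow, weightHigh,
                                seed = .subSeed(seed, k, 1))
    W1 <- edgeWeights(pg$graph)
    set.seed(.subSeed(seed, k, 2))
    W2 <- .applySessionNoise(W1, noise)
    graphs[[s]] <- list("1" = pg$graph, "2" = Connectome(W2))
    gt[[s]] <- pg$partition
    if (withStacks) {
      prof <- similarityProfile
      coords <- {
        set.seed(.subSeed(seed, k, 3))
        matrix(runif(3 * nNodes, 0, 100), nNodes, 3)
      }
      args1 <- list(base = pg$graph, seed = .subSeed(seed, k, 4), coords = coords)
      args2 <- list(base = Connectome(W2), seed = .subSeed(seed, k, 5),
                    coords = coords)
      if (!is.null(prof)) {
        args1$similarityProfile <- prof
        args2$similarityProfile <- prof
      }
      stacks[[s]] <- list("1" = do.call(generateMetricStack, args1),
                          "2" = do.call(generateMetricStack, args2))
    }
  }
  new("Cohort", subjects = subjects, graphs = graphs, stacks = stacks,
      groundTruth = gt)
}
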