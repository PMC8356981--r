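# Surrogate null models preserving degree and (approximately) strength, and
# the partition-quality permutation tests built on them.

#' Degree- and strength-preserving surrogate graph
#'
#' Randomises the topology by seeded degree-preserving double-edge swaps
#' (`nSwapsPerEdge * |E|` attempts; swaps that would disconnect the graph are
#' rejected), then reassigns the original weight multiset to the new edges by
#' rank-matching (heavier weights to edges between stronger nodes) followed by
#' iterative proportional adjustment, so every node's strength matches the
#' original within a small relative tolerance. The achieved maximum relative
#' strength error is recorded in the `"strengthError"` attribute of the
#' returned weight matrix.
#'
#' @param x a connected [Connectome-class] or weight matrix.
#' @param nSwapsPerEdge swap attempts per edge (default 10).
#' @param seed integer RNG seed.
#' @param tol relative strength tolerance targeted by the adjustment.
#' @param maxIter maximum proportional-adjustment iterations.
#' @return A [Connectome-class] with identical degree sequence and node
#'   strengths within `tol` (typically much closer).
#' @export
#' @examples
#' g <- plantedPartitionGraph(20, c(10, 10), 0.8, 0.1, seed = 2)$graph
#' s <- strengthPreservingNull(g, seed = 5)
#' all.equal(rowSums(edgeWeights(s) > 0), rowSums(edgeWeights(g) > 0))
strengthPreservingNull <- function(x, nSwapsPerEdge = 10, seed = 1,
                                   tol = 1e-3, maxIter = 200) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  if (!.isConnected(W)) stop("null model requires a connected input graph")
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0)
  edges <- cbind(row(W)[ut], col(W)[ut])
  wts <- W[ut]
  strength <- rowSums(W)
  .seedGuard(seed)
  edges2 <- .rewireConnected(edges, n, as.integer(nSwapsPerEdge * length(ut)))
  # rank-match: heaviest weights onto edges joining the strongest nodes
  score <- strength[edges2[, 1]] * strength[edges2[, 2]]
  ordEdges <- order(-score, edges2[, 1], edges2[, 2])
  newW <- matrix(0, n, n)
  idx <- cbind(edges2[ordEdges, 1], edges2[ordEdges, 2])
  newW[idx] <- sort(wts, decreasing = TRUE)
  newW <- newW + t(newW)
  # iterative proportional adjustment toward the target strengths
  for (it in seq_len(maxIter)) {
    s <- rowSums(newW)
    ratio <- ifelse(s > 0, strength / s, 1)
    err <- max(abs(s - strength) / pmax(strength, .Machine$double.eps))
    if (err <= tol) break
    scale <- sqrt(outer(ratio, ratio))
    newW <- newW * scale
    newW <- (newW + t(newW)) / 2
  }
  s <- rowSums(newW)
  attr(newW, "strengthError") <-
    max(abs(s - strength) / pmax(strength, .Machine$double.eps))
  if (is(x, "Connectome")) {
    out <- Connectome(newW, nodeLabels(x))
    attr(out@weights, "strengthError") <- attr(newW, "strengthError")
    out
  } else newW
}

#' Generate an ensemble of surrogate graphs
#'
#' @param x a connected [Connectome-class] or weight matrix.
#' @param n number of surrogates.
#' @param seed master seed; surrogate b uses a sub-seed derived from it.
#' @param nSwapsPerEdge forwarded to [strengthPreservingNull()].
#' @return list of [Connectome-class] surrogates (or matrices, matching the
#'   input kind).
#' @export
surrogateEnsemble <- function(x, n = 1000, seed = 1, nSwapsPerEdge = 10) {
  lapply(seq_len(n), function(b)
    strengthPreservingNull(x, nSwapsPerEdge = nSwapsPerEdge,
                           seed = .subSeed(seed, 11, b)))
}

#' Permutation test of partition quality against surrogate nulls
#'
#' Runs hard community detection on the observed graph and on `nSurrogates`
#' degree/strength-preserving surrogates; the add-one permutation p-value is
#' `p = (1 + #\{Q_surr >= Q_obs\}) / (nSurrogates + 1)`. A small p indicates
#' the observed modular quality is not explained by degree/strength structure.
#'
#' @param x a connected [Connectome-class] or weight matrix.
#' @param algorithm registered hard algorithm name.
#' @param scale optional scale override.
#' @param nSurrogates number of surrogates (>= 100).
#' @param seed integer master seed.
#' @param nSwapsPerEdge swap attempts per edge for the surrogates.
#' @param nRestarts optimizer restarts used for every detection run.
#' @return list with `Q`, `pValue`, `nSurrogates`.
#' @export
qualityPermutationTest <- function(x, algorithm = "newman", scale = NULL,
                                   nSurrogates = 1000, seed = 1,
                                   nSwapsPerEdge = 5, nRestarts = 1) {
  if (nSurrogates < 99) stop("nSurrogates must be at least 99")
  spec <- .algoSpec(algorithm)
  if (spec$soft)
    stop("soft algorithms have no Q index; use softNullSimilarityTest()")
  obs <- detectCommunities(x, algorithm, scale = scale,
                           seed = .subSeed(seed, 13, 0), nRestarts = nRestarts)
  Qsurr <- vapply(seq_len(nSurrogates), function(b) {
    s <- strengthPreservingNull(x, nSwapsPerEdge = nSwapsPerEdge,
                                seed = .subSeed(seed, 11, b))
    detectCommunities(s, algorithm, scale = scale,
                      seed = .subSeed(seed, 13, b),
                      nRestarts = nRestarts)$quality@Q
  }, numeric(1))
  list(Q = obs$quality@Q,
       pValue = (1 + sum(Qsurr >= obs$quality@Q)) / (nSurrogates + 1),
       nSurrogates = as.integer(nSurrogates))
}

#' Mean null similarity for soft covers
#'
#' Detects the soft cover of the observed graph, then for each surrogate
#' detects its cover and computes the cover NMI with the original; low mean
#' values indicate the observed cover is not an artifact of degree/strength
#' structure.
#'
#' @inheritParams qualityPermutationTest
#' @return list with `meanNullNmi` and `nSurrogates`.
#' @export
softNullSimilarityTest <- function(x, nSurrogates = 1000, seed = 1,
                                   nSwapsPerEdge = 5) {
  if (nSurrogates < 99) stop("nSurrogates must be at least 99")
  cov0 <- detectSoftCover(x)
  vals <- vapply(seq_len(nSurrogates), function(b) {
    s <- strengthPreservingNull(x, nSwapsPerEdge = nSwapsPerEdge,
                                seed = .subSeed(seed, 11, b))
    nmiCover(cov0, detectSoftCover(s))
  }, numeric(1))
  list(meanNullNmi = mean(vals), nSurrogates = as.integer(nSurrogates))
}
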