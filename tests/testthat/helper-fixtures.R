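# Fixture graphs and independent oracles used across the suite.

# symmetric matrix from an edge list (i, j, w)
edgeMatrix <- function(n, edges) {
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    W[edges[e, 1], edges[e, 2]] <- edges[e, 3]
    W[edges[e, 2], edges[e, 1]] <- edges[e, 3]
  }
  W
}

cliqueMatrix <- function(n, w = 1) {
  W <- matrix(w, n, n)
  diag(W) <- 0
  W
}

# two k-cliques joined by a single bridge edge
twoCliqueBridge <- function(k = 4, bridgeWeight = 0.01) {
  W <- matrix(0, 2 * k, 2 * k)
  W[1:k, 1:k] <- cliqueMatrix(k)
  W[(k + 1):(2 * k), (k + 1):(2 * k)] <- cliqueMatrix(k)
  W[k, k + 1] <- W[k + 1, k] <- bridgeWeight
  W
}

pathMatrix <- function(n, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- w
  W
}

cycleMatrix <- function(n, w = 1) {
  W <- pathMatrix(n, w)
  W[1, n] <- W[n, 1] <- w
  W
}

# connected random weighted graph (for property sweeps)
randomConnectedGraph <- function(n, p, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < p
  W[ut[on]] <- runif(sum(on), 0.2, 1)
  W <- W + t(W)
  comp <- netRepeat:::.componentsOf(W)
  while (max(comp) > 1) {
    a <- min(which(comp == 1)); b <- min(which(comp == 2))
    W[a, b] <- W[b, a] <- 0.2
    comp <- netRepeat:::.componentsOf(W)
  }
  W
}

# the small connected graphs (<= 8 nodes) used for exhaustive-oracle checks
smallGraphSet <- function() {
  list(
    path4 = pathMatrix(4),
    cycle5 = cycleMatrix(5),
    k4 = cliqueMatrix(4),
    star6 = edgeMatrix(6, cbind(1, 2:6, 1)),
    twoK3 = {
      W <- matrix(0, 6, 6)
      W[1:3, 1:3] <- cliqueMatrix(3)
      W[4:6, 4:6] <- cliqueMatrix(3)
      W[3, 4] <- W[4, 3] <- 1
      W
    },
    twoK4weak = twoCliqueBridge(4, 0.01),
    rand7 = randomConnectedGraph(7, 0.5, seed = 42),
    rand8 = randomConnectedGraph(8, 0.4, seed = 43),
    weighted8 = randomConnectedGraph(8, 0.6, seed = 44)
  )
}

# all set partitions of n elements as label vectors (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  recur <- function(labels, maxUsed) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(maxUsed + 1))
      recur(c(labels, lab), max(maxUsed, lab))
  }
  recur(integer(0), 0L)
  out
}

# exhaustive-search oracle: globally optimal criterion value over all
# partitions (independent of the greedy optimizer)
exhaustiveBestQ <- function(W, criterion = "newman", scale = 1) {
  parts <- allPartitions(nrow(W))
  max(vapply(parts, function(p) criterionValue(W, p, criterion, scale),
             numeric(1)))
}

# hand/entropy NMI oracle computed from first principles
nmiOracle <- function(l1, l2) {
  n <- length(l1)
  H <- function(l) {
    p <- table(l) / n
    -sum(p * log(p))
  }
  joint <- table(l1, l2) / n
  Hj <- -sum(joint[joint > 0] * log(joint[joint > 0]))
  I <- H(l1) + H(l2) - Hj
  if (H(l1) + H(l2) == 0) return(1)
  2 * I / (H(l1) + H(l2))
}

# default planted-partition test graph (the study's benchmark condition)
benchmarkGraph <- function(seed) {
  plantedPartitionGraph(40, rep(10, 4), pIn = 0.8, pOut = 0.05, seed = seed)
}
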