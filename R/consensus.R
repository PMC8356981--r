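# Consensus clustering: co-clustering counts across the cohort and sessions,
# OMST-filtered probability matrix, representative partition, and its
# similarity to the individual partitions.

#' Build a consensus matrix from a collection of hard partitions
#'
#' counts[i, j] is the number of partitions in which nodes i and j carry the
#' same community label; probabilities (see [coProbabilities()]) are counts
#' divided by the number of partitions (subjects x sessions), so a pair
#' observed together in every partition reaches probability 1.
#'
#' @param partitions non-empty list of [HardPartition-class] objects (or label
#'   vectors) sharing node count and ordering.
#' @return A [ConsensusMatrix-class].
#' @export
#' @examples
#' cm <- buildConsensusMatrix(list(c(1, 1, 2), c(1, 2, 2)))
#' coProbabilities(cm)
buildConsensusMatrix <- function(partitions) {
  if (length(partitions) == 0) stop("partition list must be non-empty")
  labs <- lapply(partitions, .labelsOf)
  n <- length(labs[[1]])
  if (any(vapply(labs, length, integer(1)) != n))
    stop("all partitions must share the node count")
  counts <- matrix(0, n, n)
  for (l in labs) counts <- counts + outer(l, l, `==`)
  diag(counts) <- length(labs)
  new("ConsensusMatrix", counts = counts,
      nObservations = as.integer(length(labs)))
}

#' Representative partition from a consensus matrix
#'
#' The probability matrix (diagonal zeroed — self-loops are meaningless to
#' spanning trees) is topologically filtered with [omstFilter()] in place of
#' an arbitrary threshold, and the chosen community-detection algorithm is run
#' on the filtered graph. The result is the group-representative partition.
#'
#' @param consensus a [ConsensusMatrix-class].
#' @param algorithm registered hard algorithm name (by convention the same
#'   algorithm whose partitions built the consensus).
#' @param scale optional scale override.
#' @param seed integer seed for the detection sweep order.
#' @param maxTrees forwarded to [omstFilter()].
#' @return A [HardPartition-class].
#' @export
consensusPartition <- function(consensus, algorithm = "newman", scale = NULL,
                               seed = 1, maxTrees = 10) {
  stopifnot(is(consensus, "ConsensusMatrix"))
  P <- coProbabilities(consensus)
  diag(P) <- 0
  # perfect agreement: every pair co-clusters always or never, so the blocks
  # of the probability matrix are the representative partition and running a
  # detection algorithm could only (spuriously) subdivide them
  if (all(P == 0 | P == 1)) {
    spec <- .algoSpec(algorithm)
    return(HardPartition(.componentsOf(P), algorithm = algorithm,
                         scale = if (is.null(scale)) spec$scale else scale))
  }
  comp <- .componentsOf(P)
  if (max(comp) == 1) {
    filt <- omstFilter(P, maxTrees = maxTrees)@filtered
    return(detectCommunities(filt, algorithm, scale = scale,
                             seed = seed)$partition)
  }
  # disconnected consensus: components never co-cluster across, so they are
  # partitioned independently and the labels concatenated
  labels <- integer(length(comp))
  offset <- 0L
  spec <- .algoSpec(algorithm)
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    if (length(idx) == 1L) {
      labels[idx] <- offset + 1L
      offset <- offset + 1L
    } else {
      sub <- P[idx, idx, drop = FALSE]
      filt <- omstFilter(sub, maxTrees = maxTrees)@filtered
      part <- detectCommunities(filt, algorithm, scale = scale,
                                seed = .subSeed(seed, 17, k))$partition
      labels[idx] <- offset + communityLabels(part)
      offset <- offset + nCommunities(part)
    }
  }
  HardPartition(labels, algorithm = algorithm,
                scale = if (is.null(scale)) spec$scale else scale)
}

#' Mean similarity of a representative partition to individual partitions
#'
#' @param representative a [HardPartition-class].
#' @param partitions non-empty list of individual [HardPartition-class]
#'   objects (or label vectors).
#' @return mean [nmiHard()] between the representative and each individual.
#' @export
consensusIndividualSimilarity <- function(representative, partitions) {
  if (length(partitions) == 0) stop("partition list must be non-empty")
  mean(vapply(partitions, function(p) nmiHard(representative, p), numeric(1)))
}
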