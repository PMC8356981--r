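# Generics and accessors for the core containers.

#' Edge-weight matrix of a graph-like object
#' @param x a [Connectome-class] or [OmstResult-class].
#' @return numeric matrix of edge weights.
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname edgeWeights
#' @export
setMethod("edgeWeights", "Connectome", function(x) x@weights)

#' @rdname edgeWeights
#' @export
setMethod("edgeWeights", "OmstResult", function(x) x@filtered@weights)

#' Node labels
#' @param x an object holding nodes.
#' @return character vector of node names.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "Connectome", function(x) x@nodeLabels)

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "MetricStack", function(x) x@nodeLabels)

#' Number of nodes
#' @param x an object holding nodes.
#' @return integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "Connectome", function(x) nrow(x@weights))

#' @rdname nNodes
#' @export
setMethod("nNodes", "MetricStack", function(x) nrow(x@metrics[[1]]))

#' @rdname nNodes
#' @export
setMethod("nNodes", "HardPartition", function(x) length(x@labels))

#' @rdname nNodes
#' @export
setMethod("nNodes", "SoftCover", function(x) nrow(x@membership))

#' @rdname nNodes
#' @export
setMethod("nNodes", "ConsensusMatrix", function(x) nrow(x@counts))

#' Community labels of a hard partition
#' @param x a [HardPartition-class].
#' @return integer vector of community ids (contiguous, starting at 1).
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname communityLabels
#' @export
setMethod("communityLabels", "HardPartition", function(x) x@labels)

#' Number of communities
#' @param x a [HardPartition-class] or [SoftCover-class].
#' @return integer community count.
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname nCommunities
#' @export
setMethod("nCommunities", "HardPartition", function(x) max(x@labels))

#' @rdname nCommunities
#' @export
setMethod("nCommunities", "SoftCover", function(x) ncol(x@membership))

#' Membership matrix of a soft cover
#' @param x a [SoftCover-class].
#' @return nodes x communities matrix.
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname memberships
#' @export
setMethod("memberships", "SoftCover", function(x) x@membership)

#' Co-clustering counts of a consensus matrix
#' @param x a [ConsensusMatrix-class].
#' @return integer-valued matrix of co-clustering counts.
#' @export
setGeneric("coCounts", function(x) standardGeneric("coCounts"))

#' @rdname coCounts
#' @export
setMethod("coCounts", "ConsensusMatrix", function(x) x@counts)

#' Co-clustering probabilities of a consensus matrix
#'
#' counts / nObservations, with the diagonal defined as 1.
#'
#' @param x a [ConsensusMatrix-class].
#' @return numeric matrix in `[0, 1]`.
#' @export
setGeneric("coProbabilities", function(x) standardGeneric("coProbabilities"))

#' @rdname coProbabilities
#' @export
setMethod("coProbabilities", "ConsensusMatrix", function(x) {
  p <- x@counts / x@nObservations
  diag(p) <- 1
  p
})

#' Subject identifiers of a cohort
#' @param x a [Cohort-class].
#' @return character vector of subject ids.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname subjectIds
#' @export
setMethod("subjectIds", "Cohort", function(x) x@subjects)

#' Extract one subject-session graph or stack from a cohort
#'
#' @param cohort a [Cohort-class].
#' @param subject subject id (character or index).
#' @param session session, 1 or 2.
#' @return `cohortGraph`: a [Connectome-class]; `cohortStack`: a
#'   [MetricStack-class] (or NULL when the cohort has no stacks);
#'   `cohortGroundTruth`: a [HardPartition-class] or NULL.
#' @export
cohortGraph <- function(cohort, subject, session) {
  if (is.numeric(subject)) subject <- cohort@subjects[subject]
  cohort@graphs[[subject]][[as.character(session)]]
}

#' @rdname cohortGraph
#' @export
cohortStack <- function(cohort, subject, session) {
  if (is.numeric(subject)) subject <- cohort@subjects[subject]
  cohort@stacks[[subject]][[as.character(session)]]
}

#' @rdname cohortGraph
#' @export
cohortGroundTruth <- function(cohort, subject) {
  if (is.numeric(subject)) subject <- cohort@subjects[subject]
  cohort@groundTruth[[subject]]
}

setMethod("show", "Connectome", function(object) {
  w <- object@weights
  ne <- sum(w[upper.tri(w)] > 0)
  cat(sprintf("Connectome: %d nodes, %d edges, max weight %.4g\n",
              nrow(w), ne, if (ne) max(w) else 0))
})

setMethod("show", "MetricStack", function(object) {
  cat(sprintf("MetricStack: %d nodes, metrics {%s}\n",
              nrow(object@metrics[[1]]), paste(metricNames(), collapse = ", ")))
})

setMethod("show", "HardPartition", function(object) {
  cat(sprintf("HardPartition: %d nodes in %d communities%s\n",
              length(object@labels), max(object@labels),
              if (nzchar(object@algorithm))
                sprintf(" (%s)", object@algorithm) else ""))
})

setMethod("show", "SoftCover", function(object) {
  m <- object@membership > 0
  cat(sprintf("SoftCover: %d nodes, %d communities, %d multi-membership nodes\n",
              nrow(m), ncol(m), sum(rowSums(m) > 1)))
})

setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf("ConsensusMatrix: %d nodes over %d partitions\n",
              nrow(object@counts), object@nObservations))
})

setMethod("show", "OmstResult", function(object) {
  cat(sprintf("OmstResult: %d orthogonal MSTs retained, %d edges, best J = %.4f\n",
              object@nTreesUsed,
              sum(object@filtered@weights[upper.tri(object@filtered@weights)] > 0),
              max(object@costEfficiency$J)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects x 2 sessions, %d nodes%s\n",
              length(object@subjects),
              nrow(object@graphs[[1]][["1"]]@weights),
              if (length(object@stacks)) ", with metric stacks" else ""))
})

setMethod("show", "PartitionQuality", function(object) {
  cat(sprintf("PartitionQuality: Q = %.6f (%s, scale = %g)\n",
              object@Q, object@criterion, object@scale))
})
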