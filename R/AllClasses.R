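#' @import methods
#' @importFrom stats cor sd runif rnorm setNames aov pf dist hclust cutree quantile
#' @importFrom utils read.table write.table head
#' @useDynLib netRepeat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.SYM_TOL <- 1e-12

#' Metric names expected in a metric stack
#'
#' The nine per-edge white-matter metrics carried by a [MetricStack]:
#' fractional anisotropy (FA), mean diffusivity (MD), radial diffusivity (RD),
#' number of streamlines (NS), percentage of streamlines (PS), streamline
#' density (SLD), tract volume (TV), tract length (TL) and inter-node
#' Euclidean distance (ED).
#'
#' @return Character vector of the nine metric abbreviations.
#' @export
#' @examples
#' metricNames()
metricNames <- function() c("FA", "MD", "RD", "NS", "PS", "SLD", "TV", "TL", "ED")

.checkSquareMatrix <- function(w) {
  if (!is.matrix(w) || !is.numeric(w)) return("weights must be a numeric matrix")
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (anyNA(w)) return("weights must not contain NA")
  if (max(abs(w - t(w))) > .SYM_TOL) return("weights must be symmetric (tolerance 1e-12)")
  if (any(w < 0)) return("weights must be non-negative")
  if (any(diag(w) != 0)) return("diagonal must be zero")
  NULL
}

#' Connectome: a weighted undirected brain graph
#'
#' One subject-session structural brain network: a symmetric, non-negative
#' weight matrix with zero diagonal. Edge weight 0 means "no edge".
#'
#' @slot weights numeric matrix, symmetric, non-negative, zero diagonal.
#' @slot nodeLabels character vector of node (region) names.
#'
#' @aliases Connectome
#' @exportClass Connectome
setClass("Connectome",
         representation(weights = "matrix", nodeLabels = "character"),
         validity = function(object) {
           msg <- .checkSquareMatrix(object@weights)
           if (!is.null(msg)) return(msg)
           if (length(object@nodeLabels) != nrow(object@weights))
             return("nodeLabels length must match matrix dimension")
           TRUE
         })

#' Construct a Connectome
#'
#' @param weights symmetric non-negative numeric matrix with zero diagonal.
#' @param nodeLabels optional character vector of node names; defaults to
#'   `"n1".."nN"`.
#' @return A [Connectome-class] object.
#' @export
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
#' Connectome(w)
Connectome <- function(weights, nodeLabels = NULL) {
  weights <- as.matrix(weights)
  dimnames(weights) <- NULL
  if (is.null(nodeLabels)) nodeLabels <- paste0("n", seq_len(nrow(weights)))
  new("Connectome", weights = weights, nodeLabels = as.character(nodeLabels))
}

#' MetricStack: nine per-edge metric matrices for one subject-session
#'
#' Carries the nine edge-weight metrics (see [metricNames()]) sharing a common
#' zero pattern (the tractography-defined topology).
#'
#' @slot metrics named list of nine symmetric matrices.
#' @slot nodeLabels character vector of node names.
#'
#' @aliases MetricStack
#' @exportClass MetricStack
setClass("MetricStack",
         representation(metrics = "list", nodeLabels = "character"),
         validity = function(object) {
           nm <- metricNames()
           if (!setequal(names(object@metrics), nm))
             return(sprintf("metrics must be named exactly {%s}", paste(nm, collapse = ", ")))
           dims <- vapply(object@metrics, nrow, integer(1))
           if (length(unique(dims)) != 1L) return("all metric matrices must share dimensions")
           mask <- object@metrics[["NS"]] > 0
           for (m in nm) {
             msg <- .checkSquareMatrix(object@metrics[[m]])
             if (!is.null(msg)) return(sprintf("metric %s: %s", m, msg))
             if (!identical(unname(object@metrics[[m]] > 0), unname(mask)))
               return(sprintf("metric %s does not share the NS zero pattern", m))
           }
           if (length(object@nodeLabels) != dims[[1]])
             return("nodeLabels length must match matrix dimension")
           TRUE
         })

#' Construct a MetricStack
#'
#' @param metrics named list of nine symmetric non-negative matrices sharing a
#'   zero pattern (names as in [metricNames()]).
#' @param nodeLabels optional node names.
#' @return A [MetricStack-class] object.
#' @export
MetricStack <- function(metrics, nodeLabels = NULL) {
  missingM <- setdiff(metricNames(), names(metrics))
  if (length(missingM))
    stop("metrics must be named exactly {", paste(metricNames(), collapse = ", "),
         "}; missing: ", paste(missingM, collapse = ", "))
  metrics <- lapply(metrics[metricNames()], function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  })
  if (is.null(nodeLabels)) nodeLabels <- paste0("n", seq_len(nrow(metrics[[1]])))
  new("MetricStack", metrics = metrics, nodeLabels = as.character(nodeLabels))
}

#' HardPartition: one community label per node
#'
#' @slot labels integer community ids, a contiguous set starting at 1.
#' @slot algorithm character, name of the producing algorithm ("" if unknown).
#' @slot scale numeric resolution/scale parameter used (NA if none).
#'
#' @aliases HardPartition
#' @exportClass HardPartition
setClass("HardPartition",
         representation(labels = "integer", algorithm = "character", scale = "numeric"),
         validity = function(object) {
           l <- object@labels
           if (length(l) == 0L) return("labels must be non-empty")
           if (anyNA(l)) return("labels must not contain NA")
           u <- sort(unique(l))
           if (!identical(u, seq_along(u)))
             return("labels must form a contiguous id set starting at 1")
           TRUE
         })

#' Construct a HardPartition
#'
#' Labels are canonicalised to a contiguous id set (1, 2, ...) in order of
#' first appearance, so any labelling scheme is accepted.
#'
#' @param labels vector of community assignments, one per node.
#' @param algorithm optional producing algorithm name.
#' @param scale optional resolution parameter.
#' @return A [HardPartition-class] object.
#' @export
#' @examples
#' HardPartition(c("a", "a", "b", "b"))
HardPartition <- function(labels, algorithm = "", scale = NA_real_) {
  labels <- as.integer(match(labels, unique(labels)))
  new("HardPartition", labels = labels, algorithm = algorithm, scale = as.numeric(scale))
}

#' SoftCover: overlapping community membership
#'
#' A node-by-community binary membership matrix in which every node belongs to
#' at least one community and may belong to several.
#'
#' @slot membership numeric matrix (nodes x communities), entries >= 0; a node
#'   is a member of a community where its entry is positive.
#' @slot algorithm character, producing algorithm name.
#'
#' @aliases SoftCover
#' @exportClass SoftCover
setClass("SoftCover",
         representation(membership = "matrix", algorithm = "character"),
         validity = function(object) {
           m <- object@membership
           if (!is.numeric(m) || anyNA(m) || any(m < 0))
             return("membership must be a non-negative numeric matrix")
           if (ncol(m) < 1L) return("cover must have at least one community")
           if (any(rowSums(m > 0) < 1L))
             return("every node must belong to at least one community")
           TRUE
         })

#' Construct a SoftCover
#'
#' @param membership nodes x communities matrix (positive entry = membership).
#' @param algorithm optional producing algorithm name.
#' @return A [SoftCover-class] object.
#' @export
SoftCover <- function(membership, algorithm = "") {
  membership <- as.matrix(membership)
  dimnames(membership) <- NULL
  new("SoftCover", membership = membership, algorithm = algorithm)
}

#' PartitionQuality: a quality index attached to a partition
#'
#' @slot Q numeric quality value.
#' @slot criterion one of "newman", "rb", "rn", "afg", "stability".
#' @slot scale numeric scale/resolution at which Q was evaluated.
#'
#' @aliases PartitionQuality
#' @exportClass PartitionQuality
setClass("PartitionQuality",
         representation(Q = "numeric", criterion = "character", scale = "numeric"),
         validity = function(object) {
           if (!is.finite(object@Q)) return("Q must be finite")
           TRUE
         })

#' OmstResult: outcome of orthogonal-MST topological filtering
#'
#' @slot filtered the filtered [Connectome-class].
#' @slot nTreesUsed integer, number of orthogonal spanning trees retained.
#' @slot costEfficiency data.frame with columns `nTrees`, `cost`, `J` — the
#'   global cost-efficiency curve audited by the filter.
#'
#' @aliases OmstResult
#' @exportClass OmstResult
setClass("OmstResult",
         representation(filtered = "Connectome", nTreesUsed = "integer",
                        costEfficiency = "data.frame"))

#' ConsensusMatrix: co-clustering counts across a cohort
#'
#' counts[i, j] is the number of partitions in which nodes i and j share a
#' community; probabilities are counts / nObservations. The probability
#' diagonal is reported as 1 (a node always co-clusters with itself).
#'
#' @slot counts integer-valued symmetric matrix.
#' @slot nObservations integer, number of partitions (subjects x sessions).
#'
#' @aliases ConsensusMatrix
#' @exportClass ConsensusMatrix
setClass("ConsensusMatrix",
         representation(counts = "matrix", nObservations = "integer"),
         validity = function(object) {
           cts <- object@counts
           if (max(abs(cts - t(cts))) > 0) return("counts must be symmetric")
           if (any(cts < 0) || any(cts > object@nObservations))
             return("counts must lie in [0, nObservations]")
           TRUE
         })

#' Cohort: a test-retest collection of connectomes
#'
#' Holds, per subject, the session-1 and session-2 graphs, optionally the
#' nine-metric stacks, and (for synthetic cohorts) the planted ground-truth
#' partition.
#'
#' @slot subjects character subject ids.
#' @slot graphs list: `graphs[[subject]][[session]]` is a [Connectome-class]
#'   (sessions "1" and "2").
#' @slot stacks list of the same shape holding [MetricStack-class] objects,
#'   or an empty list.
#' @slot groundTruth named list of [HardPartition-class] (may be empty).
#'
#' @aliases Cohort
#' @exportClass Cohort
setClass("Cohort",
         representation(subjects = "character", graphs = "list",
                        stacks = "list", groundTruth = "list"),
         validity = function(object) {
           for (s in object@subjects) {
             g <- object@graphs[[s]]
             if (is.null(g) || !all(c("1", "2") %in% names(g)))
               return(sprintf("subject %s must have both sessions", s))
           }
           ns <- unlist(lapply(object@graphs, function(g)
             vapply(g, function(x) nrow(x@weights), integer(1))))
           if (length(unique(ns)) > 1L)
             return("all cohort matrices must share the same node count")
           TRUE
         })

#' RunConfig: configuration of a full scheme-by-algorithm grid run
#'
#' @slot cohort list describing the cohort source: either
#'   `list(type = "synthetic", nSubjects, nNodes, nModules, pIn, pOut,
#'   weightNoiseSd, rewireFraction)` or `list(type = "manifest", path = ...)`.
#' @slot schemes character vector of scheme ids (see [schemeIds()]).
#' @slot algorithms character vector of hard algorithm names.
#' @slot scales named numeric vector of per-algorithm scales (NA = default).
#' @slot nSurrogates integer, surrogates for the quality permutation test.
#' @slot nBootstrap integer, resamples for the NMI bootstrap.
#' @slot nQualityGraphs integer, subject-session graphs per pair on which the
#'   quality permutation test is run.
#' @slot referenceSparsity numeric sparsity anchoring the thresholded schemes,
#'   or the string "auto" to match the nine-metric OMST sparsity.
#' @slot zHub,pConnector numeric hub-cartography thresholds.
#' @slot seed integer master seed.
#' @slot outDir character output directory ("" = no artifacts written).
#'
#' @aliases RunConfig
#' @exportClass RunConfig
setClass("RunConfig",
         representation(cohort = "list", schemes = "character",
                        algorithms = "character", scales = "numeric",
                        nSurrogates = "integer", nBootstrap = "integer",
                        nQualityGraphs = "integer", referenceSparsity = "ANY",
                        zHub = "numeric", pConnector = "numeric",
                        seed = "integer", outDir = "character"))
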