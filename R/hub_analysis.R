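# Hub cartography: participation coefficient, within-module z-score,
# connector/provincial classification, and the cross-cohort agreement index.
#
# All quantities are strength-based (weighted degrees), consistent with
# weighted structural brain networks.

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2` where `kappa_is` is the strength of
#' node i toward module s and `k_i` its total strength (Guimera-Amaral form on
#' weighted degrees). Nodes with zero strength get `P = 0` by convention.
#' `P = 0` means all strength stays inside the node's own module; equal
#' spread over k modules gives `P = 1 - 1/k`.
#'
#' @param x a [Connectome-class] or weight matrix.
#' @param partition a [HardPartition-class] or label vector.
#' @return numeric vector in `[0, 1]`, one value per node.
#' @export
participationCoefficient <- function(x, partition) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  labels <- .labelsOf(partition)
  if (length(labels) != nrow(W)) stop("partition must cover all nodes")
  k <- rowSums(W)
  mods <- sort(unique(labels))
  kappa <- vapply(mods, function(s)
    rowSums(W[, labels == s, drop = FALSE]), numeric(nrow(W)))
  P <- ifelse(k > 0, 1 - rowSums((kappa / pmax(k, .Machine$double.eps))^2), 0)
  pmin(pmax(P, 0), 1)
}

#' Within-module z-score
#'
#' Standardises each node's within-module strength against its module's mean
#' and standard deviation (population sd, the Guimera-Amaral convention).
#' Modules whose within-module strengths have zero spread assign `z = 0` to
#' all members; within every module the z values are mean-centred.
#'
#' @inheritParams participationCoefficient
#' @return numeric vector of z-scores, one per node.
#' @export
withinModuleZscore <- function(x, partition) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  labels <- .labelsOf(partition)
  if (length(labels) != nrow(W)) stop("partition must cover all nodes")
  z <- numeric(nrow(W))
  for (s in unique(labels)) {
    idx <- which(labels == s)
    kin <- rowSums(W[idx, idx, drop = FALSE])
    mu <- mean(kin)
    sdev <- sqrt(mean((kin - mu)^2))
    z[idx] <- if (sdev > 0) (kin - mu) / sdev else 0
  }
  z
}

#' Classify nodes as connector hubs, provincial hubs, or neither
#'
#' A node is a hub when `z >= zHub` (boundary values count as hubs); among
#' hubs, connector when `P > pConnector`, otherwise provincial. Defaults
#' follow the Guimera-Amaral cartographic thresholds (z >= 2.5, P > 0.30).
#'
#' @param P numeric vector of participation coefficients.
#' @param z numeric vector of within-module z-scores.
#' @param zHub hub threshold on z.
#' @param pConnector connector threshold on P.
#' @return factor with levels `connector`, `provincial`, `none`.
#' @export
#' @examples
#' classifyHubs(P = c(0.6, 0.1, 0.9), z = c(3, 3, 1))
classifyHubs <- function(P, z, zHub = 2.5, pConnector = 0.30) {
  stopifnot(length(P) == length(z), is.finite(zHub), is.finite(pConnector))
  role <- ifelse(z >= zHub,
                 ifelse(P > pConnector, "connector", "provincial"),
                 "none")
  factor(role, levels = c("connector", "provincial", "none"))
}

#' Cross-cohort hub agreement index
#'
#' For each node, the fraction of subjects for which the node is detected in
#' the given role in *both* scan sessions:
#' `Agreement_i = (1/nSubjects) * sum_subjects [role in session 1 AND 2]`.
#' The value is 1 exactly when the node carries the role in both scans of
#' every subject; such nodes are the consistently detected hubs.
#'
#' @param assignments named list: `assignments[[subject]]` is a list with
#'   entries `"1"` and `"2"`, each a role factor as returned by
#'   [classifyHubs()].
#' @param role `"connector"` or `"provincial"`.
#' @return numeric vector of per-node agreement values on the grid
#'   `{0, 1/nSubjects, ..., 1}`.
#' @export
agreementIndex <- function(assignments, role = c("connector", "provincial")) {
  role <- match.arg(role)
  if (length(assignments) == 0) stop("no subjects supplied")
  hits <- lapply(names(assignments), function(s) {
    a <- assignments[[s]]
    if (is.null(a[["1"]]) || is.null(a[["2"]]))
      stop("subject ", s, " is missing a session")
    (a[["1"]] == role) & (a[["2"]] == role)
  })
  Reduce(`+`, hits) / length(hits)
}

#' Nodal modular metrics for one graph-partition pair
#'
#' Convenience wrapper computing the participation coefficient, within-module
#' z-score and hub role in one call.
#'
#' @inheritParams participationCoefficient
#' @param zHub,pConnector forwarded to [classifyHubs()].
#' @return data.frame with columns `node`, `P`, `z`, `role`.
#' @export
nodalModularMetrics <- function(x, partition, zHub = 2.5, pConnector = 0.30) {
  P <- participationCoefficient(x, partition)
  z <- withinModuleZscore(x, partition)
  labels <- if (is(x, "Connectome")) nodeLabels(x)
            else paste0("n", seq_along(P))
  data.frame(node = labels, P = P, z = z,
             role = classifyHubs(P, z, zHub, pConnector),
             stringsAsFactors = FALSE)
}
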