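# Community detection: multi-scale quality criteria, a two-phase greedy
# (Louvain-style) optimizer, and a link-community soft-cover method.
#
# Five hard criteria are supported, each reducing to (or near) Newman
# modularity at its default scale:
#   newman     - weighted Newman-Girvan modularity
#   rb         - Reichardt-Bornholdt configuration-null Potts at resolution
#                gamma (gamma = 1 recovers newman)
#   rn         - Ronhovde-Nussinov Potts with non-edge penalty gamma
#   afg        - Arenas-Fernandez-Gomez: newman on the graph with uniform
#                self-loops of weight r (scale = r; r = 0 recovers newman)
#   stability  - linearised Markov stability at time t (t = 1 recovers newman)

.CRITERIA <- c("newman", "rb", "rn", "afg", "stability")

.algoRegistry <- new.env(parent = emptyenv())

.registerDefaults <- function() {
  assign("newman",   list(criterion = "newman",    scale = 1,   soft = FALSE), .algoRegistry)
  assign("mscd_afg", list(criterion = "afg",       scale = 0,   soft = FALSE), .algoRegistry)
  assign("mscd_rb",  list(criterion = "rb",        scale = 1,   soft = FALSE), .algoRegistry)
  # rn default gamma: for weighted graphs the Potts non-edge penalty must sit
  # below the typical within-module weight per missing pair (else weakly
  # attached nodes peel off into singletons) and above the between-module
  # weight density (else modules merge); 0.25 sits centrally in that window
  # for max-1-normalised connectomes
  assign("mscd_rn",  list(criterion = "rn",        scale = 0.25, soft = FALSE), .algoRegistry)
  assign("mscd_so",  list(criterion = "stability", scale = 1,   soft = FALSE), .algoRegistry)
  assign("soft_link", list(criterion = NA_character_, scale = NA_real_, soft = TRUE), .algoRegistry)
}
.registerDefaults()

#' Community-detection algorithm registry
#'
#' The registry maps algorithm names to their quality criterion and default
#' scale. Shipped entries: `newman` (modularity baseline), `mscd_afg`,
#' `mscd_rb`, `mscd_rn`, `mscd_so` (fast multi-scale criteria) and
#' `soft_link` (link-community soft cover). Additional criteria can be
#' plugged in with `registerCommunityAlgorithm`.
#'
#' @return `communityAlgorithms()`: data.frame of registered algorithms.
#' @export
#' @examples
#' communityAlgorithms()
communityAlgorithms <- function() {
  nm <- sort(ls(.algoRegistry))
  do.call(rbind, lapply(nm, function(a) {
    e <- get(a, .algoRegistry)
    data.frame(algorithm = a, criterion = e$criterion, defaultScale = e$scale,
               soft = e$soft, stringsAsFactors = FALSE)
  }))
}

#' @rdname communityAlgorithms
#' @param name new algorithm name.
#' @param criterion one of `"newman"`, `"rb"`, `"rn"`, `"afg"`, `"stability"`.
#' @param defaultScale default scale/resolution for the criterion.
#' @export
registerCommunityAlgorithm <- function(name, criterion, defaultScale) {
  criterion <- match.arg(criterion, .CRITERIA)
  assign(name, list(criterion = criterion, scale = defaultScale, soft = FALSE),
         .algoRegistry)
  invisible(communityAlgorithms())
}

.algoSpec <- function(algorithm) {
  if (!exists(algorithm, .algoRegistry))
    stop("unknown community-detection algorithm: ", algorithm)
  get(algorithm, .algoRegistry)
}

#' Evaluate a community-quality criterion for a given partition
#'
#' @param x a [Connectome-class] or weight matrix.
#' @param partition a [HardPartition-class] or label vector covering all nodes.
#' @param criterion one of `"newman"`, `"rb"`, `"rn"`, `"afg"`, `"stability"`.
#' @param scale resolution parameter: gamma for rb/rn, self-loop weight r for
#'   afg, Markov time t for stability; ignored for newman.
#' @return numeric quality value.
#' @export
#' @examples
#' W <- matrix(1, 4, 4) - diag(4)
#' criterionValue(W, rep(1, 4), "newman")  # single community: Q = 0
criterionValue <- function(x, partition, criterion = "newman", scale = 1) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  labels <- if (is(partition, "HardPartition")) partition@labels
            else as.integer(partition)
  criterion <- match.arg(criterion, .CRITERIA)
  n <- nrow(W)
  if (length(labels) != n) stop("partition must cover all nodes")
  m2 <- sum(W)                      # 2m on weighted degrees
  if (m2 == 0) stop("graph has no edges")
  d <- rowSums(W)
  comms <- split(seq_len(n), labels)
  within <- vapply(comms, function(idx) sum(W[idx, idx, drop = FALSE]),
                   numeric(1))      # ordered-pair within weight
  dC <- vapply(comms, function(idx) sum(d[idx]), numeric(1))
  switch(criterion,
    newman = sum(within) / m2 - sum((dC / m2)^2),
    rb = (sum(within) - scale * sum(dC^2) / m2) / m2,
    rn = {
      zeros <- vapply(comms, function(idx) {
        nc <- length(idx)
        nc * (nc - 1) - sum(W[idx, idx, drop = FALSE] > 0)
      }, numeric(1))
      (sum(within) - scale * sum(zeros)) / m2
    },
    afg = {
      r <- scale
      m2p <- m2 + n * r
      dCp <- dC + r * vapply(comms, length, integer(1))
      withinP <- within + r * vapply(comms, length, integer(1))
      sum(withinP) / m2p - sum((dCp / m2p)^2)
    },
    stability = {
      t <- scale
      (1 - t) + t * sum(within) / m2 - sum((dC / m2)^2)
    })
}

.singletonQ <- function(W, criterion, scale) {
  criterionValue(W, seq_len(nrow(W)), criterion, scale)
}

#' Greedy multi-scale community detection
#'
#' Two-phase greedy maximisation of the chosen criterion: local node moves to
#' the neighbouring community with the largest positive gain until no gain
#' remains, then community aggregation, repeated until stable (the Louvain
#' strategy, generalised to all supported criteria). Sweep order is shuffled
#' from `seed`; results are deterministic for a fixed seed. Several restarts
#' with derived sub-seeds are run and the best-quality partition returned; the
#' all-in-one and singleton partitions are always evaluated as baselines, so
#' the result is never worse than either.
#'
#' @param x a connected [Connectome-class] or weight matrix.
#' @param algorithm registered algorithm name (see [communityAlgorithms()]);
#'   must be a hard algorithm.
#' @param scale optional scale override (defaults to the registry value).
#' @param seed integer seed controlling sweep order.
#' @param nRestarts number of seeded restarts (>= 1).
#' @return list with elements `partition` ([HardPartition-class]) and
#'   `quality` ([PartitionQuality-class]); `quality@Q` equals
#'   `criterionValue(x, partition)` by construction.
#' @export
#' @examples
#' g <- plantedPartitionGraph(20, c(10, 10), 0.9, 0.05, seed = 3)
#' res <- detectCommunities(g$graph, "mscd_so", seed = 1)
#' res$partition
detectCommunities <- function(x, algorithm = "newman", scale = NULL,
                              seed = 1, nRestarts = 5) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  spec <- .algoSpec(algorithm)
  if (spec$soft) stop("algorithm '", algorithm,
                      "' is a soft-cover method; use detectSoftCover()")
  if (!.isConnected(W)) stop("community detection requires a connected graph")
  scale <- if (is.null(scale)) spec$scale else scale
  criterion <- spec$criterion
  n <- nrow(W)
  m2 <- sum(W)
  d <- rowSums(W)

  if (criterion %in% c("newman", "rb", "stability")) {
    mode <- 0L
    gamma <- if (criterion == "rb") scale else 1
    tfac <- if (criterion == "stability") scale else 1
    dv <- d; twoM <- m2
  } else if (criterion == "afg") {
    mode <- 0L; gamma <- 1; tfac <- 1
    dv <- d + scale; twoM <- m2 + n * scale
  } else { # rn
    mode <- 1L; gamma <- scale; tfac <- 1
    dv <- d; twoM <- m2
  }

  best <- NULL
  bestQ <- -Inf
  for (r in seq_len(max(1L, nRestarts))) {
    set.seed(.subSeed(seed, 7, r))
    lab <- .louvainRun(W, dv, twoM, rep(1, n), mode, gamma, tfac)
    Q <- criterionValue(W, lab, criterion, scale)
    if (Q > bestQ + 1e-15) { bestQ <- Q; best <- lab }
  }
  # baselines: all-in-one and singletons
  for (lab in list(rep(1L, n), seq_len(n))) {
    Q <- criterionValue(W, lab, criterion, scale)
    if (Q > bestQ + 1e-15) { bestQ <- Q; best <- lab }
  }
  part <- HardPartition(best, algorithm = algorithm, scale = scale)
  list(partition = part,
       quality = new("PartitionQuality", Q = bestQ, criterion = criterion,
                     scale = scale))
}

#' Link-community soft cover detection
#'
#' Clusters the *edges* of the graph by single-linkage on the Jaccard
#' similarity of their endpoint neighbourhoods (inclusive of the endpoints
#' themselves), cuts the dendrogram at the level maximising the partition
#' density, and projects edge communities onto node memberships. Nodes
#' incident to edges of several edge communities become multi-membership.
#'
#' @param x a connected [Connectome-class] or weight matrix.
#' @param seed integer seed (kept for interface symmetry; the construction is
#'   deterministic).
#' @return A [SoftCover-class].
#' @export
detectSoftCover <- function(x, seed = 1) {
  W <- if (is(x, "Connectome")) edgeWeights(x) else x
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0)
  ei <- row(W)[ut]; ej <- col(W)[ut]
  M <- length(ut)
  if (M < 2) {
    return(SoftCover(matrix(1, n, 1), algorithm = "soft_link"))
  }
  A <- W > 0
  nbr <- lapply(seq_len(n), function(v) sort(c(v, which(A[v, ]))))
  # edge-edge dissimilarity: 1 - Jaccard of the non-shared endpoints'
  # inclusive neighbourhoods, for edge pairs sharing a node; 1 otherwise
  D <- matrix(1, M, M)
  incident <- vector("list", n)
  for (e in seq_len(M)) {
    incident[[ei[e]]] <- c(incident[[ei[e]]], e)
    incident[[ej[e]]] <- c(incident[[ej[e]]], e)
  }
  for (v in seq_len(n)) {
    es <- incident[[v]]
    if (length(es) < 2) next
    for (a in seq_along(es)) for (b in seq_along(es)) {
      if (a >= b) next
      e1 <- es[a]; e2 <- es[b]
      u1 <- if (ei[e1] == v) ej[e1] else ei[e1]
      u2 <- if (ei[e2] == v) ej[e2] else ei[e2]
      s <- length(intersect(nbr[[u1]], nbr[[u2]])) /
           length(union(nbr[[u1]], nbr[[u2]]))
      d <- 1 - s
      if (d < D[e1, e2]) D[e1, e2] <- D[e2, e1] <- d
    }
  }
  hc <- hclust(stats::as.dist(D), method = "single")
  # partition density (Ahn-Bagrow-Lehmann):
  # (2/M) * sum_c m_c (m_c - n_c + 1) / ((n_c - 2)(n_c - 1)), term 0 if n_c <= 2
  pd <- function(ecomm) {
    s <- vapply(split(seq_len(M), ecomm), function(es) {
      mc <- length(es)
      nc <- length(unique(c(ei[es], ej[es])))
      if (nc <= 2) 0 else mc * (mc - nc + 1) / ((nc - 2) * (nc - 1))
    }, numeric(1))
    (2 / M) * sum(s)
  }
  ks <- seq_len(M)
  dvals <- vapply(ks, function(k) pd(cutree(hc, k = k)), numeric(1))
  kBest <- ks[which.max(dvals)]
  ecomm <- cutree(hc, k = kBest)
  # project edge communities to node memberships
  comms <- sort(unique(ecomm))
  memb <- matrix(0, n, length(comms))
  for (idx in seq_along(comms)) {
    es <- which(ecomm == comms[idx])
    memb[unique(c(ei[es], ej[es])), idx] <- 1
  }
  memb <- memb[, colSums(memb) > 0, drop = FALSE]
  SoftCover(memb, algorithm = "soft_link")
}
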