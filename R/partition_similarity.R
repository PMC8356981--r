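# Partition similarity: normalised mutual information for hard partitions and
# soft covers, bootstrap significance of between-scan agreement, and
# group-level agreement summaries.

.labelsOf <- function(p) {
  if (is(p, "HardPartition")) p@labels else as.integer(match(p, unique(p)))
}

#' Normalised mutual information between two hard partitions
#'
#' `NMI = 2 I(p1; p2) / (H(p1) + H(p2))` from the contingency table of label
#' co-occurrence. Symmetric, label-invariant, in `[0, 1]`. When both
#' partitions are single-community (both entropies zero) the partitions are
#' identical up to relabelling and the value is defined as 1.
#'
#' @param p1,p2 [HardPartition-class] objects or label vectors over the same
#'   node set and ordering.
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' nmiHard(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: label-invariant
#' nmiHard(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
nmiHard <- function(p1, p2) {
  l1 <- .labelsOf(p1); l2 <- .labelsOf(p2)
  if (length(l1) != length(l2))
    stop("partitions must cover the same number of nodes")
  n <- length(l1)
  tab <- table(l1, l2) / n
  pr <- rowSums(tab); pc <- colSums(tab)
  H1 <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  H2 <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  if (H1 == 0 && H2 == 0) return(1)
  nz <- tab > 0
  I <- sum(tab[nz] * log(tab[nz] / (pr[row(tab)[nz]] * pc[col(tab)[nz]])))
  val <- 2 * I / (H1 + H2)
  min(max(val, 0), 1)
}

# binary entropy helpers for the cover NMI (log base 2; normalisation makes
# the base irrelevant but base 2 follows the original formulation)
.h <- function(p) ifelse(p > 0, -p * log2(p), 0)

#' Normalised mutual information between two soft covers
#'
#' Lancichinetti-Fortunato-Kertesz cover NMI:
#' `1 - (H(C1|C2)_norm + H(C2|C1)_norm) / 2`, where each community's
#' conditional entropy is minimised over best-matching communities of the
#' other cover, subject to the standard constraint that rules out spurious
#' matches (complementary matches are rejected). Hard partitions embedded as
#' covers give values close to, but not identical with, [nmiHard()] — the two
#' normalisations differ.
#'
#' @param c1,c2 [SoftCover-class] objects (or binary membership matrices) over
#'   the same node set.
#' @return numeric in `[0, 1]`.
#' @export
nmiCover <- function(c1, c2) {
  M1 <- if (is(c1, "SoftCover")) memberships(c1) else as.matrix(c1)
  M2 <- if (is(c2, "SoftCover")) memberships(c2) else as.matrix(c2)
  M1 <- M1 > 0; M2 <- M2 > 0
  if (nrow(M1) != nrow(M2)) stop("covers must share the node set")
  if (ncol(M1) < 1 || ncol(M2) < 1) stop("covers must be non-empty")
  n <- nrow(M1)

  condNorm <- function(X, Y) {
    # mean over communities k of H(X_k | Y) / H(X_k)
    terms <- vapply(seq_len(ncol(X)), function(k) {
      x <- X[, k]
      px <- mean(x)
      Hx <- .h(px) + .h(1 - px)
      if (Hx == 0) return(0)
      best <- Hx  # fall back to H(X_k) when no community qualifies
      for (l in seq_len(ncol(Y))) {
        y <- Y[, l]
        p11 <- mean(x & y); p10 <- mean(x & !y)
        p01 <- mean(!x & y); p00 <- mean(!x & !y)
        if (.h(p11) + .h(p00) < .h(p01) + .h(p10)) next
        py <- mean(y)
        Hxy <- .h(p11) + .h(p10) + .h(p01) + .h(p00) - (.h(py) + .h(1 - py))
        if (Hxy < best) best <- Hxy
      }
      best / Hx
    }, numeric(1))
    mean(terms)
  }

  val <- 1 - (condNorm(M1, M2) + condNorm(M2, M1)) / 2
  min(max(val, 0), 1)
}

#' Bootstrap significance of between-scan partition agreement
#'
#' Builds a null distribution for [nmiHard()] by permuting the node-to-label
#' assignment of `p2` (preserving its community-size profile) `nResamples`
#' times, and returns the add-one permutation p-value
#' `p = (1 + #\{null NMI >= observed\}) / (nResamples + 1)`.
#'
#' @param p1,p2 hard partitions over the same node set.
#' @param nResamples number of label permutations (>= 100).
#' @param seed integer RNG seed.
#' @return list with elements `nmi`, `pValue`, `nResamples`.
#' @export
bootstrapNmiPvalue <- function(p1, p2, nResamples = 999, seed = 1) {
  if (nResamples < 99) stop("nResamples must be at least 99")
  l1 <- .labelsOf(p1); l2 <- .labelsOf(p2)
  obs <- nmiHard(l1, l2)
  .seedGuard(seed)
  nullNmi <- vapply(seq_len(nResamples),
                    function(b) nmiHard(l1, sample(l2)), numeric(1))
  p <- (1 + sum(nullNmi >= obs)) / (nResamples + 1)
  list(nmi = obs, pValue = p, nResamples = as.integer(nResamples))
}

#' Group-averaged between-scan community agreement
#'
#' Mean over subjects of the NMI between the session-1 and session-2
#' partitions.
#'
#' @param cohortPartitions named list: `x[[subject]]` is a list with entries
#'   `"1"` and `"2"` holding the two sessions' [HardPartition-class] objects.
#' @return numeric mean NMI.
#' @export
groupBetweenScanAgreement <- function(cohortPartitions) {
  vals <- vapply(names(cohortPartitions), function(s) {
    ps <- cohortPartitions[[s]]
    if (is.null(ps[["1"]]) || is.null(ps[["2"]]))
      stop("subject ", s, " is missing a session")
    nmiHard(ps[["1"]], ps[["2"]])
  }, numeric(1))
  mean(vals)
}

# group-level permutation p-value for the between-scan agreement: permute
# session-2 labels within every subject, recompute the group mean
.groupAgreementPvalue <- function(cohortPartitions, nResamples = 199, seed = 1) {
  obs <- groupBetweenScanAgreement(cohortPartitions)
  .seedGuard(seed)
  l1 <- lapply(cohortPartitions, function(ps) .labelsOf(ps[["1"]]))
  l2 <- lapply(cohortPartitions, function(ps) .labelsOf(ps[["2"]]))
  nullMeans <- vapply(seq_len(nResamples), function(b) {
    mean(mapply(function(a, b2) nmiHard(a, sample(b2)), l1, l2))
  }, numeric(1))
  list(agreement = obs,
       pValue = (1 + sum(nullMeans >= obs)) / (nResamples + 1))
}
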