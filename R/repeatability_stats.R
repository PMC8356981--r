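# Test-retest reliability statistics: ICC(2,1) of nodal metrics, the two-way
# ANOVA over the scheme x algorithm grid, and the final pair ranking.

#' Two-session intra-class correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)` with k = 2
#' sessions and n subjects. Identical sessions with between-subject variance
#' give 1; fully independent sessions give values near 0; constant tables are
#' defined as 0.
#'
#' @param values numeric matrix or data.frame, subjects x 2 sessions.
#' @return numeric ICC in `[-1, 1]`.
#' @export
#' @examples
#' x <- cbind(1:10, 1:10)
#' iccTwoSession(x)  # 1: no within-subject error
iccTwoSession <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) != 2) stop("values must have exactly 2 session columns")
  n <- nrow(values)
  if (n < 3) stop("ICC needs at least 3 subjects")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  k <- 2
  grand <- mean(values)
  rowm <- rowMeans(values)
  colm <- colMeans(values)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  MSE <- sum((values - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom <= 0 || (MSR == 0 && MSE == 0)) return(0)
  (MSR - MSE) / denom
}

#' Two-way fixed-effects ANOVA over the scheme x algorithm grid
#'
#' Standard two-way ANOVA with interaction, computed with [stats::aov()].
#' P-values are reported raw and Bonferroni-adjusted across the three effects.
#' With `s` schemes and `a` algorithms, the degrees of freedom are `s - 1`,
#' `a - 1` and `(s - 1)(a - 1)`.
#'
#' @param grid data.frame with factor columns `scheme` and `algorithm` and a
#'   numeric `response`, one row per cell replicate; all cells must be
#'   populated.
#' @return data.frame with rows scheme, algorithm, interaction and columns
#'   `effect`, `df`, `F`, `p`, `pBonferroni`.
#' @export
anovaTwoWay <- function(grid) {
  stopifnot(all(c("scheme", "algorithm", "response") %in% names(grid)))
  grid$scheme <- factor(grid$scheme)
  grid$algorithm <- factor(grid$algorithm)
  if (nlevels(grid$scheme) < 2 || nlevels(grid$algorithm) < 2)
    stop("need at least 2 levels per factor")
  cells <- table(grid$scheme, grid$algorithm)
  if (any(cells == 0)) stop("unbalanced design: empty scheme x algorithm cells")
  if (var(grid$response) == 0) {
    df <- c(nlevels(grid$scheme) - 1, nlevels(grid$algorithm) - 1,
            (nlevels(grid$scheme) - 1) * (nlevels(grid$algorithm) - 1))
    return(data.frame(effect = c("scheme", "algorithm", "interaction"),
                      df = df, F = 0, p = 1, pBonferroni = 1,
                      stringsAsFactors = FALSE))
  }
  fit <- aov(response ~ scheme * algorithm, data = grid)
  tab <- summary(fit)[[1]]
  eff <- data.frame(effect = c("scheme", "algorithm", "interaction"),
                    df = tab[1:3, "Df"],
                    F = tab[1:3, "F value"],
                    p = tab[1:3, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  eff$pBonferroni <- pmin(eff$p * 3, 1)
  rownames(eff) <- NULL
  eff
}

#' Rank scheme-algorithm pairs by repeatability criteria
#'
#' Pairs are first gated on the selection criteria — group-averaged
#' between-scan NMI > 0.9, bootstrap p < .05 and quality-permutation p < .05 —
#' then ordered by consensus-individual similarity (descending), with ties
#' broken by between-scan NMI (descending) and finally by pair name.
#'
#' @param evaluations data.frame with columns `scheme`, `algorithm`,
#'   `betweenScanNmi`, `nmiP`, `qualityP`, `consensusSimilarity`.
#' @param nmiGate,alpha selection thresholds (defaults 0.9 and .05).
#' @return the input rows with a logical `selected` column added, gated rows
#'   first in rank order (an empty input is an error).
#' @export
rankPairs <- function(evaluations, nmiGate = 0.9, alpha = 0.05) {
  if (nrow(evaluations) == 0) stop("no pair evaluations supplied")
  need <- c("scheme", "algorithm", "betweenScanNmi", "nmiP", "qualityP",
            "consensusSimilarity")
  stopifnot(all(need %in% names(evaluations)))
  ev <- evaluations
  ev$selected <- ev$betweenScanNmi > nmiGate &
    ev$nmiP < alpha & !is.na(ev$qualityP) & ev$qualityP < alpha
  pairName <- paste(ev$scheme, ev$algorithm, sep = ":")
  ord <- order(!ev$selected, -ev$consensusSimilarity, -ev$betweenScanNmi,
               pairName)
  ev <- ev[ord, , drop = FALSE]
  ev$rank <- NA_integer_
  ev$rank[ev$selected] <- seq_len(sum(ev$selected))
  rownames(ev) <- NULL
  ev
}

#' Wilcoxon rank-sum comparison of two nodal ICC sets
#'
#' Helper mirroring the pairwise follow-up comparison of nodal reliability
#' between two scheme-algorithm pairs.
#'
#' @param icc1,icc2 numeric vectors of nodal ICC values.
#' @return the [stats::wilcox.test()] result.
#' @export
compareNodalIcc <- function(icc1, icc2) {
  stats::wilcox.test(icc1, icc2)
}
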