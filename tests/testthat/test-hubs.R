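test_that("participation coefficient matches its closed form", {
  # all strength inside the own module -> P = 0
  W <- smallGraphSet()$twoK3
  W[3, 4] <- W[4, 3] <- 0  # cut the bridge mentally: rebuild as block graph
  W <- matrix(0, 6, 6); W[1:3, 1:3] <- cliqueMatrix(3); W[4:6, 4:6] <- cliqueMatrix(3)
  diag(W) <- 0
  P <- participationCoefficient(W, rep(1:2, each = 3))
  expect_equal(P, rep(0, 6))
  # strength split equally between 2 modules -> P = 0.5
  W2 <- edgeMatrix(3, rbind(c(1, 2, 1), c(1, 3, 1)))
  P2 <- participationCoefficient(W2, c(1, 1, 2))
  expect_equal(P2[1], 1 - 2 * 0.5^2)
  # equal split across k modules -> P = 1 - 1/k
  for (k in 2:5) {
    Wk <- edgeMatrix(k + 1, cbind(1, 2:(k + 1), 1))
    Pk <- participationCoefficient(Wk, c(1, seq_len(k) + 1))
    expect_equal(Pk[1], 1 - 1 / k)
  }
  expect_error(participationCoefficient(W2, c(1, 2)), "cover")
})

test_that("within-module z-score matches the hand mean/sd oracle", {
  # uniform clique: zero within-module variance -> all z = 0
  z <- withinModuleZscore(cliqueMatrix(4), rep(1, 4))
  expect_equal(z, rep(0, 4))
  # star module: within-strengths {3,1,1,1}; population sd oracle:
  # mean = 1.5, sd = sqrt(((3-1.5)^2 + 3*(1-1.5)^2)/4) = sqrt(0.75)
  W <- edgeMatrix(4, cbind(1, 2:4, 1))
  z2 <- withinModuleZscore(W, rep(1, 4))
  expect_equal(z2[1], (3 - 1.5) / sqrt(0.75))
  expect_equal(z2[2], (1 - 1.5) / sqrt(0.75))
  # module z values centre to zero
  for (seed in 1:5) {
    Wr <- randomConnectedGraph(20, 0.4, seed = 300 + seed)
    lab <- rep(1:4, each = 5)
    zr <- withinModuleZscore(Wr, lab)
    for (s in 1:4) expect_lt(abs(sum(zr[lab == s])), 1e-9)
  }
})

test_that("P and z are invariant under global weight rescaling", {
  W <- randomConnectedGraph(20, 0.4, seed = 310)
  lab <- rep(1:4, each = 5)
  expect_equal(participationCoefficient(W, lab),
               participationCoefficient(3.7 * W, lab), tolerance = 1e-12)
  expect_equal(withinModuleZscore(W, lab),
               withinModuleZscore(3.7 * W, lab), tolerance = 1e-12)
})

test_that("hub classification applies the cartographic thresholds", {
  roles <- classifyHubs(P = c(0.6, 0.1, 0.9, 0.5), z = c(3, 3, 1, 2.5))
  expect_identical(as.character(roles),
                   c("connector", "provincial", "none", "connector"))
  # boundary contract: z exactly at the threshold counts as a hub
  expect_identical(as.character(classifyHubs(0.1, 2.5)), "provincial")
  expect_identical(as.character(classifyHubs(0.31, 2.49)), "none")
})

test_that("agreement index implements the per-subject two-scan intersection", {
  mk <- function(roles) factor(roles, levels = c("connector", "provincial", "none"))
  # node 1 connector in both sessions for all subjects -> 1
  # node 2 connector only in session 1 -> 0
  # node 3 connector in both sessions for half the subjects -> 0.5
  assignments <- list()
  for (k in 1:20) {
    s1 <- mk(c("connector", "connector",
               if (k <= 10) "connector" else "none"))
    s2 <- mk(c("connector", "none",
               if (k <= 10) "connector" else "none"))
    assignments[[sprintf("s%02d", k)]] <- list("1" = s1, "2" = s2)
  }
  agr <- agreementIndex(assignments, "connector")
  expect_equal(agr, c(1, 0, 0.5))
  expect_true(all(agr %in% ((0:20) / 20)))
  expect_error(agreementIndex(list(a = list("1" = mk("none"))), "connector"),
               "missing a session")
})

test_that("a planted high-z high-P node reaches connector agreement 1", {
  # zero-noise cohort; inject one node with strong links into every module
  coh <- testRetestCohort(4, nNodes = 40, moduleSizes = rep(10, 4),
                          noise = sessionNoiseSpec(0, 0), seed = 70)
  assignments <- list()
  for (s in subjectIds(coh)) {
    assignments[[s]] <- list()
    for (sess in c("1", "2")) {
      W <- edgeWeights(cohortGraph(coh, s, sess))
      W[1, ] <- W[, 1] <- 0
      W[1, c(2:8, 11:17, 21:27, 31:37)] <- 2.5
      W[c(2:8, 11:17, 21:27, 31:37), 1] <- 2.5
      diag(W) <- 0
      lab <- communityLabels(cohortGroundTruth(coh, s))
      met <- nodalModularMetrics(Connectome(W), lab)
      expect_gt(met$P[1], 0.30)
      assignments[[s]][[sess]] <- met$role
    }
  }
  agr <- agreementIndex(assignments, "connector")
  expect_equal(agr[1], 1)
})
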