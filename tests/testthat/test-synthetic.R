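test_that("deterministic planted graph: two cliques plus one repair bridge", {
  res <- plantedPartitionGraph(8, c(4, 4), pIn = 1, pOut = 0,
                               weightLow = 0.5, weightHigh = 0.5, seed = 1)
  W <- edgeWeights(res$graph)
  expect_identical(communityLabels(res$partition), rep(1:2, each = 4L))
  # two 4-cliques (6 edges each) plus exactly one bridging edge
  expect_equal(sum(W[upper.tri(W)] > 0), 13)
  expect_true(W[1, 5] > 0)  # bridge joins the smallest nodes of the components
  expect_true(netRepeat:::.isConnected(W))
})

test_that("realised within-module density tracks pIn", {
  res <- plantedPartitionGraph(40, rep(10, 4), pIn = 0.8, pOut = 0.05, seed = 1)
  W <- edgeWeights(res$graph)
  lab <- communityLabels(res$partition)
  ut <- upper.tri(W)
  same <- outer(lab, lab, `==`) & ut
  dens <- sum(W[same] > 0) / sum(same)
  expect_lt(abs(dens - 0.8), 0.1)
})

test_that("planted graph rejects inconsistent parameters", {
  expect_error(plantedPartitionGraph(9, c(5, 5), 0.8, 0.1), "sum to nNodes")
  expect_error(plantedPartitionGraph(10, c(5, 5), 0.5, 0.6), "pOut < pIn")
})

test_that("generated graphs are symmetric, non-negative, connected", {
  for (seed in 1:5) {
    W <- edgeWeights(plantedPartitionGraph(30, c(10, 10, 10), 0.7, 0.05,
                                           seed = seed)$graph)
    expect_identical(W, t(W))
    expect_true(all(W >= 0))
    expect_true(all(diag(W) == 0))
    expect_true(netRepeat:::.isConnected(W))
  }
})

test_that("metric stack honours the similarity profile and zero pattern", {
  g <- plantedPartitionGraph(40, rep(10, 4), 0.8, 0.05, seed = 5)$graph
  W <- edgeWeights(g)
  prof <- c(FA = 1.0, MD = 0.6, RD = 0.6, PS = 0.9, SLD = 0.8, TV = 0.7,
            TL = 0.0)
  st <- generateMetricStack(g, similarityProfile = prof, seed = 9)
  expect_identical(st@metrics[["NS"]], W)
  ut <- which(upper.tri(W) & W > 0)
  # zero-noise limit: FA is a positive linear map of NS over the edges
  expect_gt(cor(st@metrics[["FA"]][ut], W[ut]), 0.999)
  # zero-similarity limit: TL decorrelated from NS
  expect_lt(abs(cor(st@metrics[["TL"]][ut], W[ut])), 0.2)
  # inverted-scale diffusivity: MD anticorrelates with NS
  expect_lt(cor(st@metrics[["MD"]][ut], W[ut]), -0.4)
  for (m in metricNames())
    expect_identical(unname(st@metrics[[m]] > 0), unname(W > 0))
})

test_that("ED satisfies the triangle inequality on fully-present triples", {
  g <- plantedPartitionGraph(15, c(8, 7), 0.95, 0.6, seed = 2)$graph
  st <- generateMetricStack(g, seed = 3)
  ED <- st@metrics[["ED"]]
  n <- nrow(ED)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (ED[i, j] > 0 && ED[j, k] > 0 && ED[i, k] > 0) {
      expect_lte(ED[i, k], ED[i, j] + ED[j, k] + 1e-12)
    }
  }
})

test_that("metric stack rejects incomplete similarity profiles", {
  g <- plantedPartitionGraph(10, c(5, 5), 0.9, 0.1, seed = 1)$graph
  expect_error(generateMetricStack(g, similarityProfile = c(FA = 0.7)),
               "missing metric")
})

test_that("zero-noise cohorts duplicate session 1 and are seed-reproducible", {
  coh <- testRetestCohort(4, nNodes = 20, moduleSizes = rep(5, 4),
                          noise = sessionNoiseSpec(0, 0), seed = 21)
  for (s in subjectIds(coh)) {
    expect_identical(edgeWeights(cohortGraph(coh, s, 1)),
                     edgeWeights(cohortGraph(coh, s, 2)))
  }
  coh2 <- testRetestCohort(4, nNodes = 20, moduleSizes = rep(5, 4),
                           noise = sessionNoiseSpec(0, 0), seed = 21)
  expect_identical(lapply(subjectIds(coh), function(s)
    edgeWeights(cohortGraph(coh, s, 1))),
    lapply(subjectIds(coh2), function(s) edgeWeights(cohortGraph(coh2, s, 1))))
})

test_that("rewiring preserves edge count and bounds the edge-set difference", {
  f <- 0.1
  coh <- testRetestCohort(3, nNodes = 40, moduleSizes = rep(10, 4),
                          noise = sessionNoiseSpec(0, rewireFraction = f),
                          seed = 33)
  for (s in subjectIds(coh)) {
    W1 <- edgeWeights(cohortGraph(coh, s, 1))
    W2 <- edgeWeights(cohortGraph(coh, s, 2))
    e1 <- W1[upper.tri(W1)] > 0
    e2 <- W2[upper.tri(W2)] > 0
    expect_identical(sum(e1), sum(e2))          # |E| preserved
    expect_lte(sum(xor(e1, e2)), 2 * f * sum(e1))
    # degree-preserving swaps keep the degree sequence
    expect_identical(rowSums(W1 > 0), rowSums(W2 > 0))
    expect_true(netRepeat:::.isConnected(W2))
  }
})

test_that("session noise is monotone: between-scan NMI does not increase", {
  grids <- c(0, 0.15, 0.5)
  agr <- vapply(grids, function(sdev) {
    coh <- testRetestCohort(8, nNodes = 40, moduleSizes = rep(10, 4),
                            noise = sessionNoiseSpec(sdev, sdev / 2),
                            seed = 77)
    parts <- lapply(subjectIds(coh), function(s) {
      list("1" = detectCommunities(cohortGraph(coh, s, 1), "mscd_so",
                                   seed = 5)$partition,
           "2" = detectCommunities(cohortGraph(coh, s, 2), "mscd_so",
                                   seed = 5)$partition)
    })
    names(parts) <- subjectIds(coh)
    groupBetweenScanAgreement(parts)
  }, numeric(1))
  expect_equal(agr[1], 1)
  expect_true(all(diff(agr) <= 1e-12))
})
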