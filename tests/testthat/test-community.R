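test_that("criterion values match hand-computed modularity", {
  # a single community always has Newman Q = 0
  for (W in list(cliqueMatrix(5), pathMatrix(6), randomConnectedGraph(8, 0.5, 1)))
    expect_equal(criterionValue(W, rep(1, nrow(W)), "newman"), 0)
  # two disjoint K3 joined by one unit edge, partitioned into the triangles:
  # m = 7, ordered within-weight = 12, d_c = 7 each
  # Q = 12/14 - 2 * (7/14)^2 = 6/7 - 1/2 = 5/14
  W <- smallGraphSet()$twoK3
  expect_equal(criterionValue(W, rep(1:2, each = 3), "newman"), 5 / 14)
  # rb at gamma = 1 equals newman on arbitrary graph/partition pairs
  set.seed(20)
  for (i in 1:10) {
    W <- randomConnectedGraph(9, 0.4, seed = 100 + i)
    p <- sample(1:3, 9, replace = TRUE)
    expect_equal(criterionValue(W, p, "rb", 1),
                 criterionValue(W, p, "newman"), tolerance = 1e-12)
  }
  # stability at t = 1 and afg at r = 0 also reduce to newman
  W <- smallGraphSet()$twoK4weak
  p <- rep(1:2, each = 4)
  expect_equal(criterionValue(W, p, "stability", 1),
               criterionValue(W, p, "newman"), tolerance = 1e-12)
  expect_equal(criterionValue(W, p, "afg", 0),
               criterionValue(W, p, "newman"), tolerance = 1e-12)
  expect_error(criterionValue(W, p, "nope"), "arg")
})

test_that("greedy optimizer recovers two weakly-bridged cliques exactly", {
  W <- twoCliqueBridge(4, 0.01)
  res <- detectCommunities(W, "newman", seed = 3)
  expect_equal(nmiHard(res$partition, rep(1:2, each = 4)), 1)
  # and the returned Q is the global optimum found by exhaustive enumeration
  expect_equal(res$quality@Q, exhaustiveBestQ(W, "newman"), tolerance = 1e-12)
})

test_that("greedy optimizer attains the exhaustive optimum on all small fixtures", {
  for (nm in names(smallGraphSet())) {
    W <- smallGraphSet()[[nm]]
    res <- detectCommunities(W, "newman", seed = 1)
    expect_equal(res$quality@Q, exhaustiveBestQ(W, "newman"),
                 tolerance = 1e-12, label = paste("fixture", nm))
  }
})

test_that("afg resistance limits drive the partition to singletons or one block", {
  W <- smallGraphSet()$twoK3
  n <- nrow(W)
  # analytic check at the extremes of the resistance scale on a small graph
  singles <- seq_len(n); whole <- rep(1, n)
  expect_gt(criterionValue(W, singles, "afg", 1000),
            criterionValue(W, whole, "afg", 1000))
  expect_gt(criterionValue(W, whole, "afg", -2),
            criterionValue(W, singles, "afg", -2))
  resHi <- detectCommunities(W, "mscd_afg", scale = 1000, seed = 2)
  expect_identical(nCommunities(resHi$partition), n)
  resLo <- detectCommunities(W, "mscd_afg", scale = -2, seed = 2)
  expect_identical(nCommunities(resLo$partition), 1L)
})

test_that("returned quality is self-consistent and never below the baselines", {
  tab <- communityAlgorithms()
  hard <- tab$algorithm[!tab$soft]
  for (alg in hard) {
    for (seed in 1:3) {
      W <- randomConnectedGraph(15, 0.3, seed = 200 + seed)
      res <- detectCommunities(W, alg, seed = seed)
      spec <- netRepeat:::.algoSpec(alg)
      expect_equal(res$quality@Q,
                   criterionValue(W, res$partition, spec$criterion,
                                  res$quality@scale),
                   tolerance = 1e-12)
      expect_gte(res$quality@Q,
                 criterionValue(W, rep(1, 15), spec$criterion, spec$scale) - 1e-12)
      expect_gte(res$quality@Q,
                 criterionValue(W, 1:15, spec$criterion, spec$scale) - 1e-12)
    }
  }
})

test_that("fixed seeds give deterministic partitions; igraph agrees on Q", {
  g <- benchmarkGraph(5)$graph
  a <- detectCommunities(g, "mscd_so", seed = 9)
  b <- detectCommunities(g, "mscd_so", seed = 9)
  expect_identical(communityLabels(a$partition), communityLabels(b$partition))
  # independent cross-check: igraph's Louvain should reach (at least) a very
  # similar Newman modularity on the same graph
  res <- detectCommunities(g, "newman", seed = 9)
  ig <- igraph::graph_from_adjacency_matrix(edgeWeights(g),
                                            mode = "undirected",
                                            weighted = TRUE)
  set.seed(1)
  cl <- igraph::cluster_louvain(ig)
  Qig <- igraph::modularity(ig, igraph::membership(cl),
                            weights = igraph::E(ig)$weight)
  expect_equal(res$quality@Q, Qig, tolerance = 0.02)
})

test_that("soft cover: overlap node joins both cliques, rows cover every node", {
  # two 4-cliques sharing exactly node 4
  W <- matrix(0, 7, 7)
  W[1:4, 1:4] <- cliqueMatrix(4)
  W[4:7, 4:7] <- cliqueMatrix(4)
  diag(W) <- 0
  cov <- detectSoftCover(W)
  m <- memberships(cov) > 0
  expect_identical(ncol(m), 2L)
  expect_identical(sum(m[4, ]), 2L)          # the shared node is in both
  expect_true(all(rowSums(m[-4, , drop = FALSE]) == 1))
  # a single clique collapses to one community
  cov2 <- detectSoftCover(cliqueMatrix(5))
  expect_identical(ncol(memberships(cov2)), 1L)
  expect_true(all(rowSums(memberships(cov2) > 0) >= 1))
  # tiny graphs: single community cover
  cov3 <- detectSoftCover(pathMatrix(2))
  expect_identical(dim(memberships(cov3)), c(2L, 1L))
})

test_that("the algorithm registry accepts plug-ins", {
  registerCommunityAlgorithm("mscd_rb_fine", "rb", 2)
  tab <- communityAlgorithms()
  expect_true("mscd_rb_fine" %in% tab$algorithm)
  g <- benchmarkGraph(2)$graph
  res <- detectCommunities(g, "mscd_rb_fine", seed = 1)
  expect_equal(res$quality@scale, 2)
  expect_error(detectCommunities(g, "no_such_algo"), "unknown")
  expect_error(detectCommunities(g, "soft_link"), "soft")
})
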