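test_that("global efficiency matches hand-computed shortest-path values", {
  expect_equal(globalEfficiency(cliqueMatrix(4)), 1)
  expect_equal(globalEfficiency(matrix(0, 4, 4)), 0)
  # 3-node unit path: pair distances {1, 1, 2} -> mean(1, 1, 1/2) = 5/6
  expect_equal(globalEfficiency(pathMatrix(3)), 5 / 6)
  expect_error(globalEfficiency(matrix(0, 1, 1)), "at least 2")
})

test_that("OMST of a spanning tree returns the tree itself", {
  set.seed(10)
  tree <- pathMatrix(6, 1)
  tree[tree > 0] <- runif(sum(tree > 0), 0.3, 1)
  tree <- (tree + t(tree)) / 2
  res <- omstFilter(tree)
  expect_identical(edgeWeights(res), tree)
  expect_identical(res@nTreesUsed, 1L)
})

test_that("OMST equals the brute-force J-maximising prefix on weighted K5", {
  set.seed(11)
  W <- cliqueMatrix(5)
  W[upper.tri(W)] <- runif(10, 0.1, 1)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  res <- omstFilter(W, maxTrees = 4)

  # independent oracle: rebuild the orthogonal MST sequence and score every
  # prefix from scratch
  remaining <- W
  acc <- matrix(0, 5, 5)
  Js <- numeric(0)
  prefixes <- list()
  while (netRepeat:::.isConnected(remaining) && length(Js) < 4) {
    tr <- netRepeat:::.kruskalMst(remaining)
    acc[tr] <- W[tr]; acc[tr[, 2:1]] <- W[tr]
    remaining[tr] <- 0; remaining[tr[, 2:1]] <- 0
    Js <- c(Js, globalEfficiency(acc) - sum(acc) / sum(W))
    prefixes[[length(Js)]] <- acc
  }
  bestPrefix <- prefixes[[which.max(Js)]]
  expect_equal(edgeWeights(res), bestPrefix)
  expect_equal(max(res@costEfficiency$J), max(Js))
  # the returned accumulation dominates every other prefix
  expect_true(all(max(res@costEfficiency$J) >= res@costEfficiency$J))
})

test_that("OMST output is connected with between n-1 and maxTrees*(n-1) edges", {
  for (seed in 1:4) {
    W <- randomConnectedGraph(12, 0.5, seed)
    res <- omstFilter(W, maxTrees = 3)
    Wf <- edgeWeights(res)
    ne <- sum(Wf[upper.tri(Wf)] > 0)
    expect_gte(ne, 11)
    expect_lte(ne, 3 * 11)
    expect_true(netRepeat:::.isConnected(Wf))
    # surviving edges keep their original weights
    expect_true(all(Wf[Wf > 0] == W[Wf > 0]))
  }
  expect_error(omstFilter(diag(0, 4)), "connected")
  expect_error(omstFilter(cliqueMatrix(4), maxTrees = 0), "maxTrees")
})

test_that("metric integration weights dissimilar metrics more heavily", {
  g <- plantedPartitionGraph(20, c(10, 10), 0.9, 0.2, seed = 4)$graph
  # two identical metrics -> equal alphas, output proportional to the input
  prof <- c(FA = 1.0, MD = 0.6, RD = 0.6, PS = 1.0, SLD = 0.8, TV = 0.7,
            TL = 0.5)
  st <- generateMetricStack(g, similarityProfile = prof, seed = 6)
  res <- integrateMetrics(st, c("NS", "PS"))
  alpha <- attr(edgeWeights(res), "alpha")
  expect_equal(unname(alpha), c(0.5, 0.5), tolerance = 1e-12)
  # M3 uncorrelated with M1 = M2 gets the largest alpha
  prof2 <- prof; prof2[["TL"]] <- 0
  st2 <- generateMetricStack(g, similarityProfile = prof2, seed = 7)
  res2 <- integrateMetrics(st2, c("NS", "PS", "TL"))
  a2 <- attr(edgeWeights(res2), "alpha")
  expect_gt(a2[["TL"]], a2[["NS"]])
  expect_gt(a2[["TL"]], a2[["PS"]])
  expect_equal(unname(a2[["NS"]]), unname(a2[["PS"]]), tolerance = 0.05)
  expect_error(integrateMetrics(st, "NS"), "at least 2")
})

test_that("metric integration is invariant to the metric order", {
  g <- plantedPartitionGraph(20, c(10, 10), 0.9, 0.2, seed = 8)$graph
  st <- generateMetricStack(g, seed = 9)
  a <- edgeWeights(integrateMetrics(st, c("NS", "FA", "MD", "TL")))
  b <- edgeWeights(integrateMetrics(st, c("TL", "MD", "NS", "FA")))
  attr(a, "alpha") <- NULL; attr(b, "alpha") <- NULL
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("thresholding keeps the highest-weight edges deterministically", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(6, 5, 4, 3, 2, 1)
  W <- W + t(W)
  out <- thresholdToSparsity(W, 0.5)  # 3 of 6 edges
  expect_identical(sort(out[upper.tri(out)][out[upper.tri(out)] > 0]),
                   c(4, 5, 6))
  # target = current sparsity -> identity
  g <- randomConnectedGraph(10, 0.4, seed = 12)
  expect_equal(thresholdToSparsity(g, sparsityOf(g)), g)
  # all weights tied: exactly half survive, lexicographically smallest pairs
  # (1,2), (1,3), (1,4) win over (2,3), (2,4), (3,4)
  U <- cliqueMatrix(4, 1)
  half <- thresholdToSparsity(U, 0.5)
  expect_identical(sum(half[upper.tri(half)] > 0), 3L)
  expect_identical(which(half > 0, arr.ind = TRUE)[1:3, ],
                   cbind(row = c(2L, 3L, 4L), col = c(1L, 1L, 1L)))
  expect_error(thresholdToSparsity(pathMatrix(4), 1), "cannot reach")
})

test_that("the seven schemes obey their Table-2 structure", {
  g <- plantedPartitionGraph(30, rep(10, 3), 0.85, 0.1, seed = 14)$graph
  st <- generateMetricStack(g, seed = 15)
  D <- applyScheme("D", st, referenceSparsity = 0.15)
  E <- applyScheme("E", st, referenceSparsity = 0.15)
  Fh <- applyScheme("F", st, referenceSparsity = 0.15)
  # D, E and F share an identical topology, differing only in weights
  expect_identical(edgeWeights(D) > 0, edgeWeights(E) > 0)
  expect_identical(edgeWeights(D) > 0, edgeWeights(Fh) > 0)
  expect_false(identical(edgeWeights(D), edgeWeights(E)))
  # C is connected by the OMST guarantee
  C <- applyScheme("C", st)
  expect_true(netRepeat:::.isConnected(edgeWeights(C)))
  # with "auto", sparsity(D) equals sparsity(C) exactly
  Dauto <- applyScheme("D", st, referenceSparsity = "auto")
  expect_identical(sum(edgeWeights(Dauto) > 0), sum(edgeWeights(C) > 0))
  # every scheme output is symmetric, zero-diagonal, max weight 1
  for (sym in schemeIds()$symbol) {
    out <- edgeWeights(applyScheme(sym, st, referenceSparsity = 0.15))
    expect_identical(out, t(out))
    expect_true(all(diag(out) == 0))
    expect_equal(max(out), 1)
  }
  expect_error(applyScheme("Z", st), "unknown")
})
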