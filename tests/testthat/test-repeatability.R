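test_that("ICC(2,1) hits its closed-form landmarks", {
  # duplicated sessions with subject variance: no error variance -> 1
  expect_equal(iccTwoSession(cbind(1:10, 1:10)), 1)
  # constant table: defined as 0
  expect_equal(iccTwoSession(cbind(rep(2, 5), rep(2, 5))), 0)
  expect_error(iccTwoSession(cbind(1:2, 1:2)), "at least 3")
  expect_error(iccTwoSession(matrix(1:9, 3, 3)), "2 session")
  expect_error(iccTwoSession(cbind(c(1, NA, 3), 1:3)), "finite")
})

test_that("independent sessions give near-zero ICC; noise degrades ICC monotonically", {
  set.seed(40)
  x <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(iccTwoSession(x)), 0.15)
  # subject signal + increasing session-2 noise
  subjectEffect <- rnorm(60)
  iccs <- vapply(c(0.1, 0.5, 1.5), function(sd2) {
    set.seed(41)
    iccTwoSession(cbind(subjectEffect + rnorm(60, 0, 0.1),
                        subjectEffect + rnorm(60, 0, sd2)))
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("two-way ANOVA reports the expected structure and df", {
  set.seed(42)
  schemes <- paste0("S", 1:7)
  algos <- paste0("A", 1:4)
  grid <- expand.grid(scheme = schemes, algorithm = algos,
                      rep = 1:5, KEEP.OUT.ATTRS = FALSE)
  grid$response <- rnorm(nrow(grid))
  res <- anovaTwoWay(grid)
  expect_equal(res$df, c(6, 3, 18))
  # constant response -> all F = 0
  grid0 <- grid; grid0$response <- 1
  res0 <- anovaTwoWay(grid0)
  expect_true(all(res0$F == 0))
  expect_equal(res0$df, c(6, 3, 18))
  # guards
  expect_error(anovaTwoWay(grid[grid$scheme == "S1", ]), "2 levels")
  expect_error(anovaTwoWay(grid[!(grid$scheme == "S1" &
                                    grid$algorithm == "A1"), ]), "empty")
})

test_that("ANOVA recovers a planted scheme main effect with power", {
  set.seed(43)
  hits <- replicate(100, {
    grid <- expand.grid(scheme = paste0("S", 1:4), algorithm = paste0("A", 1:3),
                        rep = 1:4, KEEP.OUT.ATTRS = FALSE)
    effect <- c(S1 = 0, S2 = 0.5, S3 = 1, S4 = 1.5)
    grid$response <- effect[as.character(grid$scheme)] + rnorm(nrow(grid), 0, 0.5)
    res <- anovaTwoWay(grid)
    c(scheme = res$p[1] < 0.05, algorithm = res$p[2] < 0.05)
  })
  expect_gte(mean(hits["scheme", ]), 0.9)   # planted effect detected
  expect_lte(mean(hits["algorithm", ]), 0.2)  # absent effect near alpha
})

test_that("pair ranking gates on NMI and p-values, then orders by consensus", {
  ev <- data.frame(
    scheme = c("C", "A", "D", "B"),
    algorithm = c("mscd_so", "mscd_so", "mscd_rb", "mscd_afg"),
    betweenScanNmi = c(0.95, 0.92, 0.95, 0.95),
    nmiP = c(0.001, 0.001, 0.001, 0.001),
    qualityP = c(0.01, 0.01, 0.2, 0.01),
    consensusSimilarity = c(0.75, 0.70, 0.9, 0.75))
  r <- rankPairs(ev)
  expect_false(r$selected[r$scheme == "D"])    # quality gate excludes D
  sel <- r[r$selected, ]
  # B and C tie on consensus (0.75) and NMI (0.95); pair name breaks the tie
  expect_identical(sel$scheme[1:2], c("B", "C"))
  # ties on consensusSimilarity resolved by NMI, then pair name
  expect_identical(sel$consensusSimilarity, sort(sel$consensusSimilarity,
                                                 decreasing = TRUE))
  expect_identical(sel$rank, seq_len(nrow(sel)))
  one <- rankPairs(ev[2, , drop = FALSE])
  expect_identical(one$rank, 1L)
  expect_error(rankPairs(ev[0, ]), "no pair")
})
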