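test_that("logarithmic trend fitting and extrapolation are exact", {
  f <- fitLogTrend(1:10, 2 * log(1:10) + 1)
  expect_equal(c(f$a, f$b), c(2, 1), tolerance = 1e-12)
  ## constant series: zero slope, intercept at the mean
  fc <- fitLogTrend(1:8, rep(3.5, 8))
  expect_equal(c(fc$a, fc$b), c(0, 3.5), tolerance = 1e-12)
  ## transfer indices starting at 0 are shifted to start at 1
  f0 <- fitLogTrend(0:9, 2 * log(1:10) + 1)
  expect_equal(f0$a, 2, tolerance = 1e-12)
  expect_error(fitLogTrend(0:4, 1:5, shift = FALSE), "non-positive")
  ## extrapolation
  expect_equal(extrapolateTrend(list(a = 2, b = 1), exp(1)), 3)
  expect_gt(extrapolateTrend(f, 40), extrapolateTrend(f, 20))
  expect_error(extrapolateTrend(f, 0.5), ">= 1")
})

test_that("simulator trajectories produce increasing well-fitting log trends", {
  cfg <- SimulationConfig()             # default study length, 100 transfers
  tr <- simulateLineageTrajectory(cfg)
  set.seed(5)
  y <- tr$trueMu * (1 + rnorm(nrow(tr), 0, cfg@measurementNoiseCv))
  f <- fitLogTrend(tr$transfer, y)
  expect_gt(f$a, 0)
  expect_gt(f$r2, 0.8)
  ## extrapolating an increasing fit beyond the horizon exceeds the endpoint
  expect_gt(extrapolateTrend(f, 2 * max(f$x)), tail(f$fitted, 1))
})

test_that("fold changes are endpoint/origin ratios and scale-invariant", {
  rec <- data.frame(transfer = c(0, 10, 20), growthRate = c(0.4, 0.5, 0.6),
                    meanAR = c(0.4, 0.5, 0.6), meanL = 3:1, meanW = c(1, 1, 1))
  tr <- LineageTrajectory("L1", "oleate_vesicle", rec)
  expect_equal(foldChanges(tr, "meanAR")$fold, 1.5)
  expect_equal(foldChanges(tr, "meanW")$fold, 1)
  ## multiplying a feature by a constant leaves folds unchanged
  rec2 <- rec; rec2$meanAR <- rec$meanAR * 7.3
  tr2 <- LineageTrajectory("L1", "oleate_vesicle", rec2)
  expect_equal(foldChanges(tr2, "meanAR")$fold,
               foldChanges(tr, "meanAR")$fold)
  rec0 <- rec; rec0$meanAR[1] <- 0
  expect_error(foldChanges(LineageTrajectory("x", "g", rec0), "meanAR"),
               "origin")
})

test_that("permutation p-values match complete enumeration", {
  ## identical constant groups
  expect_equal(permutationTest(rep(2, 4), rep(2, 4))$p, 1)
  ## 6 vs 6 with zero overlap: only the two extreme splits are as extreme
  res <- permutationTest(1:6, 101:106)
  expect_true(res$exact)
  expect_equal(res$nSplits, 924)
  expect_equal(res$p, 2 / 924)
  ## agreement with an independent brute-force oracle on random groups
  set.seed(40)
  for (i in 1:4) {
    a <- rnorm(5); b <- rnorm(4, mean = 0.5)
    expect_equal(permutationTest(a, b)$p, enumPermOracle(a, b))
  }
  ## Monte Carlo path approximates the exact answer
  set.seed(41)
  a <- rnorm(30); b <- rnorm(30, 1.2)
  pm <- permutationTest(a, b, nPerm = 2000)
  expect_false(pm$exact)
  expect_lt(pm$p, 0.05)
})

test_that("fold-change group comparison reports permutation and Welch results", {
  res <- compareFoldChangeGroups(c(1.9, 2.1, 2.0, 2.2, 1.8, 2.05),
                                 c(1.0, 1.1, 0.95, 1.05, 1.0, 0.9))
  expect_equal(res$p, 2 / 924)
  expect_true(is.finite(res$welch_t))
  expect_lt(res$welch_p, 0.001)
  expect_error(compareFoldChangeGroups(c(1, 2), c(1, 2, 3)), "at least 3")
})
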