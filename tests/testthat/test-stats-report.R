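makeRecords <- function(n, f = NULL) {
  rec <- data.frame(transfer = seq_len(n) - 1, growthRate = rnorm(n),
                    meanAR = rnorm(n), meanL = rnorm(n), meanW = rnorm(n),
                    meanLogA = rnorm(n), meanLogV = rnorm(n))
  if (!is.null(f)) rec[names(f)] <- f
  rec
}

test_that("correlation matrices satisfy their structural invariants", {
  set.seed(50)
  cm <- featureCorrelations(makeRecords(12))
  expect_true(validObject(cm))
  expect_equal(diag(cm@r), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(abs(cm@r) <= 1, na.rm = TRUE))
  expect_equal(cm@r, t(cm@r))
  ## duplicated feature: r = 1 with p at the numerical floor
  rec <- makeRecords(10)
  rec$meanAR <- rec$growthRate
  cm2 <- featureCorrelations(rec)
  expect_equal(cm2@r["growth", "aspect"], 1)
  expect_lt(cm2@p["growth", "aspect"], 1e-12)
  ## exact anticorrelation
  rec$meanL <- -rec$growthRate
  expect_equal(featureCorrelations(rec)@r["growth", "length"], -1)
  ## constant feature: undefined pairs reported missing with p = 1
  rec3 <- makeRecords(10, list(meanW = rep(2, 10)))
  cm3 <- featureCorrelations(rec3)
  expect_true(is.na(cm3@r["width", "growth"]))
  expect_equal(cm3@p["width", "growth"], 1)
})

test_that("correlation p-values agree with an exact permutation oracle", {
  ## oracle: permute one variable over all n! orderings and count |r*| >= |r|
  permCorOracle <- function(x, y) {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
      out
    }
    robs <- abs(cor(x, y))
    rs <- vapply(perms(seq_along(y)),
                 function(p) abs(cor(x, y[p])), numeric(1))
    mean(rs >= robs - 1e-12)
  }
  set.seed(51)
  for (i in 1:3) {
    x <- rnorm(6); y <- 0.8 * x + rnorm(6, 0, 0.6)
    pT <- cor.test(x, y)$p.value
    pPerm <- permCorOracle(x, y)
    expect_lt(abs(pT - pPerm), 0.1)
  }
})

test_that("group comparison matches enumeration and reports box statistics", {
  a <- c(5, 6, 7, 8, 9, 10)
  expect_equal(compareGroups(a, a)$p, 1)
  ## a constant positive shift making 6 vs 6 disjoint: p = 2/924
  res <- compareGroups(a + 100, a)
  expect_equal(res$p, 2 / 924)
  expect_equal(unname(res$means), c(mean(a) + 100, mean(a)))
  ## paired sign-flip test against explicit enumeration
  set.seed(52)
  x <- rnorm(7); y <- x + rnorm(7, 0.8, 0.3)
  rp <- compareGroups(y, x, paired = TRUE)
  d <- y - x
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 7)))
  oracle <- mean(abs(signs %*% d / 7) >= abs(mean(d)) - 1e-12)
  expect_equal(rp$p, oracle)
})

test_that("boxplot summaries use exact type-7 order statistics", {
  s <- summarizeBoxes(1:5, rep("a", 5))
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  expect_equal(s$q1, 2)
  ## single value: all statistics equal it
  s1 <- summarizeBoxes(4.2, "x")
  expect_true(all(s1[, c("min", "q1", "median", "q3", "max", "mean")] == 4.2))
  ## bookkeeping: one row per group
  set.seed(53)
  s12 <- summarizeBoxes(rnorm(120), rep(paste0("p", 1:12), each = 10))
  expect_equal(nrow(s12), 12L)
})
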