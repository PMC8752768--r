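#' @include AllClasses.R
NULL

#' Logarithmic trend of a trajectory feature
#'
#' Least-squares fit of `y = a * ln(x) + b`, the saturating trend used to
#' summarize temporal changes of growth rate and cell shape over transfers
#' or generations. The abscissa is shifted to start at 1 (so a transfer
#' index starting at 0 is admissible) unless `shift = FALSE`.
#'
#' @param x transfer or generation index (at least 3 points).
#' @param y feature series.
#' @param shift shift `x` to start at 1.
#' @return list with `a`, `b`, `r2`, `fitted`, and the shifted abscissa `x`.
#' @examples
#' f <- fitLogTrend(1:10, 2 * log(1:10) + 1)
#' c(f$a, f$b)
#' @export
fitLogTrend <- function(x, y, shift = TRUE) {
  if (length(x) != length(y)) stop("x and y must match in length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (shift) x <- x - min(x) + 1
  if (any(x <= 0)) stop("non-positive index after shift")
  lx <- log(x)
  f <- stats::lm(y ~ lx)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst < 1e-24) 1 else 1 - sum(stats::resid(f)^2) / sst
  list(a = unname(stats::coef(f)[2]), b = unname(stats::coef(f)[1]),
       r2 = r2, fitted = unname(stats::fitted(f)), x = x)
}

#' Extrapolate a logarithmic trend
#'
#' Evaluates `a * ln(x) + b` at future indices; with `a > 0` the prediction
#' keeps increasing, the basis for predicting that extended evolution would
#' further raise growth rate and aspect ratio.
#'
#' @param fit result of [fitLogTrend()].
#' @param xFuture indices (`>= 1`, on the shifted scale).
#' @return predicted values.
#' @export
extrapolateTrend <- function(fit, xFuture) {
  if (any(xFuture < 1)) stop("xFuture must be >= 1 on the shifted scale")
  fit$a * log(xFuture) + fit$b
}

#' Endpoint/origin fold changes per lineage
#'
#' For each lineage trajectory, the ratio of the endpoint (final measured
#' transfer) mean of a feature to its origin (ancestral) mean.
#'
#' @param trajectories list of [LineageTrajectory-class] objects.
#' @param feature column of the trajectory records (e.g. `"growthRate"`,
#'   `"meanAR"`).
#' @return data.frame with columns `lineage`, `condition`, `feature`,
#'   `origin`, `endpoint`, `fold`.
#' @export
foldChanges <- function(trajectories, feature = "growthRate") {
  if (is(trajectories, "LineageTrajectory")) trajectories <- list(trajectories)
  rows <- lapply(trajectories, function(tr) {
    stopifnot(is(tr, "LineageTrajectory"))
    rec <- tr@records
    if (!feature %in% names(rec))
      stop("feature not in trajectory records: ", feature)
    if (nrow(rec) < 2L) stop("trajectory needs an origin and an endpoint")
    o <- rec[[feature]][1L]
    e <- rec[[feature]][nrow(rec)]
    if (!is.finite(o) || o == 0) stop("origin mean is zero or undefined")
    data.frame(lineage = tr@lineage, condition = tr@condition,
               feature = feature, origin = o, endpoint = e, fold = e / o)
  })
  do.call(rbind, rows)
}

#' Two-sided permutation test on the difference of group means
#'
#' Exact (complete enumeration of all group relabellings) whenever the
#' number of splits is small enough -- e.g. all `choose(12, 6) = 924`
#' splits for two groups of six lineages -- and Monte Carlo otherwise.
#' The p-value is the fraction of relabellings whose absolute mean
#' difference is at least the observed one (the observed labelling counts
#' itself, so `p >= 1/nSplits`); identical constant groups give `p = 1`.
#'
#' @param a,b numeric group values.
#' @param nPerm Monte Carlo permutations when enumeration is infeasible.
#' @param exactLimit maximum number of splits to enumerate.
#' @return list with `statistic` (mean(a) - mean(b)), `p`, `exact`
#'   (logical), and `nSplits`.
#' @examples
#' permutationTest(1:6, 7:12)$p    # 2/924: only the two extreme splits
#' @export
permutationTest <- function(a, b, nPerm = 10000L, exactLimit = 50000L) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need at least 2 values per group")
  pool <- c(a, b)
  obs <- mean(a) - mean(b)
  ## mean difference is monotone in sum(group A): work with sums
  tol <- 1e-12 * max(1, abs(obs), stats::sd(pool))
  nSplit <- choose(na + nb, na)
  if (nSplit <= exactLimit) {
    idx <- utils::combn(na + nb, na)
    sums <- colSums(matrix(pool[idx], nrow = na))
    stats <- sums / na - (sum(pool) - sums) / nb
    p <- mean(abs(stats) >= abs(obs) - tol)
    list(statistic = obs, p = p, exact = TRUE, nSplits = nSplit)
  } else {
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      s <- sample(pool)
      st <- mean(s[seq_len(na)]) - mean(s[-seq_len(na)])
      if (abs(st) >= abs(obs) - tol) cnt <- cnt + 1L
    }
    list(statistic = obs, p = (cnt + 1) / (nPerm + 1), exact = FALSE,
         nSplits = nPerm)
  }
}

#' Compare fold changes between the two evolution arms
#'
#' Two-sided exact permutation test on the difference of group mean fold
#' changes (oleate-vesicle lineages versus glucose lineages), with a Welch
#' t-test reported alongside as a parametric cross-check. With six
#' lineages per arm the permutation test enumerates all 924 splits.
#'
#' @param oavFolds,glcFolds numeric fold changes, one per lineage
#'   (at least 3 each).
#' @param ... passed to [permutationTest()].
#' @return list with `statistic`, `p` (permutation), `exact`, `nSplits`,
#'   `welch_t`, `welch_p`.
#' @export
compareFoldChangeGroups <- function(oavFolds, glcFolds, ...) {
  if (length(oavFolds) < 3L || length(glcFolds) < 3L)
    stop("need at least 3 fold changes per group")
  pt <- permutationTest(oavFolds, glcFolds, ...)
  wt <- try(stats::t.test(oavFolds, glcFolds), silent = TRUE)
  if (inherits(wt, "try-error")) {
    welchT <- NA_real_; welchP <- NA_real_
  } else {
    welchT <- unname(wt$statistic); welchP <- wt$p.value
  }
  c(pt, list(welch_t = welchT, welch_p = welchP))
}
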