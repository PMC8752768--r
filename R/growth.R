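#' @include AllClasses.R
NULL

#' Estimate the exponential growth rate of a culture
#'
#' Sliding-window log-linear regression: the growth rate is the slope of
#' `ln(density)` versus time over the window of consecutive points that
#' maximizes the slope subject to a linearity floor (`R^2 >= r2Floor`).
#' If no window is linear enough, the best-`R^2` window is returned with a
#' low-confidence flag. A constant series returns rate 0 with the flag.
#'
#' OD-mode curves are treated identically: the rate only needs the log
#' scale, not absolute densities.
#'
#' @param curve a [GrowthCurve-class] (at least 4 time points).
#' @param window window size in points (default 5).
#' @param r2Floor minimum within-window `R^2`.
#' @return list with `mu` (per hour), `window` = `c(tStart, tEnd)` (hours),
#'   `r2`, and `lowConfidence`.
#' @examples
#' gc <- simulateGrowthCurve(0.5, 1e5, 1e8, times = seq(0, 20, 0.5))
#' fitGrowthRate(gc)$mu
#' @export
fitGrowthRate <- function(curve, window = 5L, r2Floor = 0.99) {
  stopifnot(is(curve, "GrowthCurve"))
  keep <- curve@densities > 0
  tt <- curve@times[keep]
  y <- log(curve@densities[keep])
  n <- length(tt)
  if (n < 4L) stop("need at least 4 positive-density time points")
  w <- min(window, n)
  if (stats::sd(y) < 1e-12)
    return(list(mu = 0, window = range(tt), r2 = NA_real_,
                lowConfidence = TRUE))
  starts <- seq_len(n - w + 1L)
  fits <- lapply(starts, function(s) {
    i <- s:(s + w - 1L)
    f <- stats::lm(y[i] ~ tt[i])
    sst <- sum((y[i] - mean(y[i]))^2)
    list(mu = unname(stats::coef(f)[2]),
         r2 = if (sst < 1e-24) 0 else 1 - sum(stats::resid(f)^2) / sst,
         t = range(tt[i]))
  })
  mus <- vapply(fits, `[[`, numeric(1), "mu")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  ok <- r2s >= r2Floor
  if (any(ok)) {
    best <- which(ok)[which.max(mus[ok])]
    low <- FALSE
  } else {
    best <- which.max(r2s)
    low <- TRUE
  }
  list(mu = mus[best], window = fits[[best]]$t, r2 = r2s[best],
       lowConfidence = low)
}

#' Carrying capacity per unit carbon
#'
#' The maximal cell concentration (cells/mL) divided by the supplied carbon
#' concentration (mM) -- the carbon-utilization efficiency statistic. The
#' maximum is taken on a 3-point median-smoothed series to guard against
#' single-point spikes; if the maximum falls on the final time point, no
#' plateau was observed and the result is flagged.
#'
#' @param curve a [GrowthCurve-class] with positive `carbonmM`.
#' @return list with `capacity` (cells/mL per mM), `maxDensity`,
#'   `plateau` (`FALSE` when the maximum is the final point) and
#'   `relative` (`TRUE` for OD-mode curves, whose capacity is only
#'   relative).
#' @export
carryingCapacity <- function(curve) {
  stopifnot(is(curve, "GrowthCurve"))
  if (curve@carbonmM <= 0) stop("carbonmM must be positive")
  d <- curve@densities
  if (!length(d)) stop("empty curve")
  sm <- if (length(d) >= 3) stats::runmed(d, 3) else d
  i <- which.max(sm)
  list(capacity = sm[i] / curve@carbonmM, maxDensity = sm[i],
       plateau = i < length(sm), relative = curve@od)
}

#' Carbon-equivalent concentration
#'
#' Converts a molar substrate concentration into carbon-atom equivalents:
#' glucose (C6H12O6) carries 6 carbon atoms per molecule and oleate
#' (C18H34O2) 18, so oleate carries threefold more carbon per molecule.
#' This puts the two concentration ladders of the resource-utilization
#' assay (0.035-3.5 mM oleate vesicles; 0.105-10.5 mM glucose) on a common
#' carbon-mM axis.
#'
#' @param conc concentration, mM (vectorized, `>= 0`).
#' @param source `"glucose"` or `"oleate_vesicle"` (alias `"oleate"`),
#'   recycled against `conc`.
#' @return carbon-equivalent concentration, carbon-mM.
#' @examples
#' normalizeCarbon(10.5, "glucose")          # 63
#' normalizeCarbon(3.5, "oleate_vesicle")    # 63
#' @export
normalizeCarbon <- function(conc, source) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  atoms <- c(glucose = 6, oleate = 18, oleate_vesicle = 18)
  src <- as.character(source)
  if (!all(src %in% names(atoms)))
    stop("unknown carbon source: ", paste(setdiff(src, names(atoms)),
                                          collapse = ", "))
  conc * unname(atoms[src])
}

#' Cubic trend of carrying capacity over concentration
#'
#' Least-squares cubic polynomial regression of capacity on
#' log10(concentration), the theoretical analysis used to summarize how
#' carbon-utilization efficiency changes across the concentration ladder.
#'
#' @param concentrations mM (at least 4 distinct values).
#' @param capacities matching capacities.
#' @return list with `coef` (intercept and the three polynomial
#'   coefficients), `fitted`, `logConc`, and `r2`.
#' @export
fitCapacityTrend <- function(concentrations, capacities) {
  if (length(concentrations) != length(capacities))
    stop("concentrations and capacities must match in length")
  if (length(unique(concentrations)) < 4L)
    stop("need at least 4 distinct concentrations for a cubic fit")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  x <- log10(concentrations)
  f <- stats::lm(capacities ~ x + I(x^2) + I(x^3))
  sst <- sum((capacities - mean(capacities))^2)
  r2 <- if (sst < 1e-24) 1 else 1 - sum(stats::resid(f)^2) / sst
  list(coef = stats::setNames(stats::coef(f), c("b0", "b1", "b2", "b3")),
       fitted = unname(stats::fitted(f)), logConc = x, r2 = r2)
}
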