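#' @include AllClasses.R capsule.R
NULL

## exponential relaxation toward the evolved target with the configured
## half-life (transfers); the generative law behind all parameter trajectories
relaxTo <- function(start, target, t, halflife) {
  target + (start - target) * 2^(-t / halflife)
}

#' Simulate the true parameter trajectory of one evolving lineage
#'
#' Plays the daily serial-transfer protocol forward for one lineage: each
#' day the culture is split at three candidate dilution factors, grown for
#' 24 h (logistic growth toward the stationary density), and the one culture
#' still within the exponential phase whose density is closest to the
#' exponential-phase target is selected for the next day. Post-dilution
#' densities below the drift floor are never admissible. Cumulative
#' generations are accounted as `log2` of each day's regrowth fold.
#'
#' True cell parameters (mean length/width, growth rate, GFP concentration)
#' relax from their ancestral values toward the evolved targets with the
#' configured half-life; this function returns the noiseless ground truth,
#' one row per transfer (row `transfer = 0` is the common ancestor).
#'
#' @param config a [SimulationConfig-class].
#' @param lineageId character id recorded in the output.
#' @return data.frame with columns `lineage`, `transfer`, `trueL`, `trueW`,
#'   `trueMu` (per hour), `trueGfp` (a.u./um^3), `dilution`, `n0`, `nEnd`
#'   (cells/mL), `dailyGenerations` and cumulative `generations`.
#' @examples
#' cfg <- SimulationConfig(nTransfers = 10L)
#' tr <- simulateLineageTrajectory(cfg)
#' tail(tr$generations, 1)  # generations accumulated over 10 transfers
#' @export
simulateLineageTrajectory <- function(config, lineageId = "L1") {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nT <- config@nTransfers
  hl <- config@trajectoryHalflife
  K  <- config@stationaryDensity
  target <- config@exponentialTarget
  floorN <- config@driftFloor
  ts <- 0:nT
  L   <- relaxTo(config@morphologyStart["meanL"], config@morphologyTarget["meanL"], ts, hl)
  W   <- relaxTo(config@morphologyStart["meanW"], config@morphologyTarget["meanW"], ts, hl)
  mu  <- relaxTo(config@fitnessStart, config@fitnessTarget, ts, hl)
  gfp <- relaxTo(config@gfpStart, config@gfpTarget, ts, hl)

  dilution <- rep(NA_real_, nT + 1)
  n0 <- rep(NA_real_, nT + 1)
  nEnd <- rep(NA_real_, nT + 1)
  gen <- rep(0, nT + 1)
  nEnd[1] <- target                       # ancestor stocked in exponential phase
  logistic24 <- function(N0, mu) K / (1 + (K / N0 - 1) * exp(-mu * 24))
  for (t in seq_len(nT)) {
    muDay <- mu[t + 1]
    opts <- if (config@adaptiveDilution) {
      ## three factors bracketing the regrowth predicted from the previous
      ## day's growth rate, as when dilution rates are chosen daily;
      ## clamped so the drift floor is respected
      dStar <- nEnd[t] * exp(mu[t] * 24) / target
      pmin(dStar * c(1 / 3, 1, 3), nEnd[t] / floorN)
    } else config@dilutionOptions
    opts <- pmax(opts, 1.0001)            # a transfer always dilutes
    ok <- nEnd[t] / opts >= floorN
    if (!any(ok))
      stop("non-viable protocol: no dilution keeps the culture above the drift floor")
    opts <- unique(opts[ok])
    N0c <- nEnd[t] / opts
    N24 <- logistic24(N0c, muDay)
    expo <- N24 <= 0.5 * K                # below stationary onset
    pick <- if (any(expo)) {
      cand <- which(expo)
      cand[which.min(abs(log(N24[cand] / target)))]
    } else which.min(N24)
    dilution[t + 1] <- opts[pick]
    n0[t + 1] <- N0c[pick]
    nEnd[t + 1] <- N24[pick]
    gen[t + 1] <- gen[t] + log2(N24[pick] / N0c[pick])
  }
  data.frame(lineage = lineageId, transfer = ts,
             trueL = unname(L), trueW = unname(W), trueMu = mu, trueGfp = gfp,
             dilution = dilution, n0 = n0, nEnd = nEnd,
             dailyGenerations = c(0, diff(gen)), generations = gen,
             row.names = NULL)
}

#' Render a single-cell image
#'
#' Draws the 2D projection of a spherocylinder of length `L` and width `W`
#' (a capsule: a rectangle with half-disc caps) on a pixel grid, with
#' anti-aliased Gaussian edges. Total fluorescence integrates to
#' `gfp * V * gain` before noise, where `V = (pi/6) L W^2` is the
#' spherocylinder volume of the generating parameters. Defocus is modelled
#' as a widening of the edge-spread profile by `focusBlur` pixels (an
#' effective edge-spread model: for a convex capsule this matches Gaussian
#' blurring of the support to good accuracy and is much cheaper).
#'
#' @param L,W major and minor axis lengths, micrometres (`L >= W > 0`).
#' @param orientation radians.
#' @param gfp GFP concentration, a.u. per cubic micrometre.
#' @param focusBlur defocus blur sigma, pixels (0 = in focus).
#' @param noiseCv multiplicative intensity noise CV.
#' @param pixelArea square micrometres per pixel (0.09 by default, the
#'   instrument's calibration at 60x).
#' @param gain detector gain, a.u.
#' @param backgroundNoise additive background noise sigma, as a fraction of
#'   the peak signal.
#' @param phase subpixel offset of the cell centre relative to the pixel
#'   grid, in pixels; `NULL` draws it uniformly.
#' @param label,inFocus ground-truth annotation recorded in the event.
#' @param edge intrinsic edge-spread sigma, pixels.
#' @return a [CellImage-class].
#' @examples
#' img <- renderCellImage(3, 1, orientation = 0.4, noiseCv = 0)
#' sum(fluorChannel(img)) / computeVolume(3, 1)  # ~ gfp * gain
#' @export
renderCellImage <- function(L, W, orientation = 0, gfp = 100,
                            focusBlur = 0, noiseCv = 0.05,
                            pixelArea = 0.09, gain = 1,
                            backgroundNoise = 0.01, phase = NULL,
                            label = "cell", inFocus = focusBlur < 1,
                            edge = 0.5) {
  if (!is.finite(L) || !is.finite(W) || W <= 0 || L < W)
    stop("require L >= W > 0: the major axis must be the longer dimension")
  px <- sqrt(pixelArea)
  if (is.null(phase)) phase <- stats::runif(2, -0.5, 0.5)
  pad <- 6 + ceiling(3 * focusBlur)
  n <- ceiling(L / px) + 2L * pad
  ctr <- ((n + 1) / 2 + phase) * px
  xs <- seq_len(n) * px
  g <- expand.grid(x = xs, y = xs)
  d <- capsuleSignedDistance(g$x, g$y, ctr[1], ctr[2], orientation,
                             a = (L - W) / 2, r = W / 2)
  sigma <- sqrt(edge^2 + focusBlur^2) * px
  cov <- matrix(capsuleProfile(d, sigma), n, n)
  support <- cov
  scale <- gfp * computeVolume(L, W) * gain / sum(cov)
  fluor <- cov * scale
  if (noiseCv > 0 || backgroundNoise > 0) {
    fluor <- fluor * (1 + stats::rnorm(length(fluor), 0, noiseCv)) +
      stats::rnorm(length(fluor), 0, backgroundNoise * scale)
    fluor <- pmax(fluor, 0)
  }
  new("CellImage", fluor = fluor, mask = support, pixelArea = pixelArea,
      label = label, inFocus = inFocus,
      truth = list(L = L, W = W, orientation = orientation, gfp = gfp,
                   gain = gain, focusBlur = focusBlur))
}

## calibration bead: small sharp disc, dim in the GFP channel (SpeedBead-like
## reagents fluoresce mainly in other channels)
renderBead <- function(diameter = 1, intensity = 8, pixelArea = 0.09,
                       noiseCv = 0.05) {
  px <- sqrt(pixelArea)
  n <- ceiling(diameter / px) + 12L
  ctr <- ((n + 1) / 2 + stats::runif(2, -0.5, 0.5)) * px
  xs <- seq_len(n) * px
  g <- expand.grid(x = xs, y = xs)
  d <- capsuleSignedDistance(g$x, g$y, ctr[1], ctr[2], 0, 0, diameter / 2)
  cov <- matrix(capsuleProfile(d, 0.35 * px), n, n)
  fluor <- cov * intensity / sum(cov)
  if (noiseCv > 0) fluor <- pmax(fluor * (1 + stats::rnorm(length(fluor), 0, noiseCv)), 0)
  new("CellImage", fluor = fluor, mask = cov, pixelArea = pixelArea,
      label = "bead", inFocus = TRUE,
      truth = list(diameter = diameter, intensity = intensity))
}

## culture debris: an irregular dim blob built from a few random Gaussian
## lobes; total intensity well below the cellular range
renderDebris <- function(intensity = 5, pixelArea = 0.09, noiseCv = 0.05) {
  px <- sqrt(pixelArea)
  n <- 24L
  xs <- seq_len(n) * px
  g <- expand.grid(x = xs, y = xs)
  nl <- sample(3:6, 1)
  ctr <- (n / 2) * px
  img <- 0
  for (i in seq_len(nl)) {
    cx <- ctr + stats::rnorm(1, 0, 0.6)
    cy <- ctr + stats::rnorm(1, 0, 0.6)
    s <- stats::runif(1, 0.1, 0.4)
    img <- img + stats::runif(1, 0.2, 1) *
      exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * s^2))
  }
  img <- matrix(img, n, n)
  fluor <- img * intensity / sum(img)
  if (noiseCv > 0) fluor <- pmax(fluor * (1 + stats::rnorm(length(fluor), 0, noiseCv)), 0)
  new("CellImage", fluor = fluor, mask = img / max(img),
      pixelArea = pixelArea, label = "debris", inFocus = TRUE,
      truth = list(intensity = intensity, lobes = nl))
}

#' Sample an imaged population for one transfer
#'
#' Draws `nEvents` events for a population with true mean length/width and
#' GFP concentration taken from a ground-truth record: cell dimensions are
#' lognormal about the true means (with `W <= L` enforced by resampling),
#' orientations uniform, and the declared fractions of calibration beads,
#' culture debris and out-of-focus cells are interleaved at random
#' positions. Ground-truth labels stay attached to each event so gating can
#' be scored.
#'
#' @param truth one-row data.frame (or list) with `trueL`, `trueW`,
#'   `trueGfp`, as returned by [simulateLineageTrajectory()]; a plain
#'   numeric `c(L, W, gfp)` also works.
#' @param nEvents events to draw (the instrument acquires ~10,000).
#' @param contaminantFractions named fractions `bead`, `debris`,
#'   `outOfFocus`, summing to < 1.
#' @param cvL,cvW lognormal CVs of cell length and width.
#' @param gfpCv lognormal CV of per-cell GFP concentration.
#' @param pixelArea,noiseCv,focusBlurSigma rendering parameters; see
#'   [renderCellImage()].
#' @param lineage,transfer,condition sample annotation.
#' @return a [PopulationSample-class].
#' @export
samplePopulation <- function(truth, nEvents = 10000,
                             contaminantFractions = c(bead = 0.05,
                                                      debris = 0.05,
                                                      outOfFocus = 0.10),
                             cvL = 0.15, cvW = 0.15, gfpCv = 0.2,
                             pixelArea = 0.09, noiseCv = 0.05,
                             focusBlurSigma = 2,
                             lineage = "L1", transfer = 0L,
                             condition = "oleate_vesicle") {
  if (nEvents <= 0) stop("nEvents must be positive")
  cf <- contaminantFractions
  if (is.null(names(cf))) names(cf) <- c("bead", "debris", "outOfFocus")
  if (any(cf < 0) || sum(cf) >= 1)
    stop("contaminant fractions must be >= 0 and sum to < 1")
  if (is.numeric(truth) && is.null(dim(truth)) && length(truth) >= 3 &&
      is.null(names(truth)))
    truth <- list(trueL = truth[1], trueW = truth[2], trueGfp = truth[3])
  mL <- truth$trueL; mW <- truth$trueW; mg <- truth$trueGfp
  stopifnot(is.finite(mL), is.finite(mW), mW <= mL)

  type <- sample(c("bead", "debris", "oof", "cell"), nEvents, replace = TRUE,
                 prob = c(cf[["bead"]], cf[["debris"]], cf[["outOfFocus"]],
                          1 - sum(cf)))
  rln <- function(n, mean, cv) {
    if (cv <= 0) return(rep(mean, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
  }
  evs <- vector("list", nEvents)
  for (i in seq_len(nEvents)) {
    evs[[i]] <- switch(type[i],
      bead = renderBead(pixelArea = pixelArea, noiseCv = noiseCv,
                        intensity = rln(1, 8, 0.1)),
      debris = renderDebris(pixelArea = pixelArea, noiseCv = noiseCv,
                            intensity = rln(1, 5, 0.5)),
      {
        repeat {                           # enforce W <= L by resampling
          Li <- rln(1, mL, cvL); Wi <- rln(1, mW, cvW)
          if (Wi <= Li) break
        }
        renderCellImage(Li, Wi, orientation = stats::runif(1, 0, pi),
                        gfp = rln(1, mg, gfpCv),
                        focusBlur = if (type[i] == "oof") focusBlurSigma else 0,
                        noiseCv = noiseCv, pixelArea = pixelArea)
      })
  }
  new("PopulationSample", events = evs, lineage = as.character(lineage),
      transfer = as.integer(transfer), condition = as.character(condition))
}

#' Simulate a logistic growth curve
#'
#' Density follows `N(t) = K / (1 + (K/N0 - 1) exp(-mu t))` with optional
#' multiplicative lognormal noise, emulating temporal density measurements
#' of a batch culture monitored until stationary phase.
#'
#' @param rate growth rate mu, per hour.
#' @param inoculum starting density N0, cells/mL (`inoculum < capacity`).
#' @param capacity carrying capacity K, cells/mL.
#' @param times sampling times, hours (non-empty).
#' @param noiseCv multiplicative noise CV.
#' @param carbonSource,carbonmM,replicate curve annotation.
#' @return a [GrowthCurve-class].
#' @export
simulateGrowthCurve <- function(rate, inoculum, capacity, times,
                                noiseCv = 0,
                                carbonSource = c("oleate_vesicle", "glucose"),
                                carbonmM = 3.5, replicate = "r1") {
  if (!length(times)) stop("times must be non-empty")
  if (rate <= 0 || inoculum <= 0 || capacity <= 0)
    stop("rate, inoculum and capacity must be positive")
  if (inoculum >= capacity) stop("inoculum must be below capacity")
  N <- capacity / (1 + (capacity / inoculum - 1) * exp(-rate * times))
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    N <- N * stats::rlnorm(length(N), -sdlog^2 / 2, sdlog)
  }
  GrowthCurve(times, N, carbonSource = match.arg(carbonSource),
              carbonmM = carbonmM, replicate = replicate)
}
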