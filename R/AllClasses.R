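## Central S4 data containers. Validity methods enforce the geometric and
## protocol invariants; constructors carry the defaults that describe the
## serial-transfer evolution experiment the simulator emulates.

#' SimulationConfig: parameters of the simulated evolution experiment
#'
#' Describes one arm of a serial-transfer evolution experiment: how many
#' lineages and daily transfers, the carbon source, the dilution protocol,
#' and how the true cell parameters (morphology, growth rate, GFP
#' concentration) relax from their ancestral values toward the evolved
#' targets.
#'
#' The trajectory law is an exponential relaxation with half-life
#' `trajectoryHalflife` (in transfers): a parameter at transfer `t` equals
#' `target + (start - target) * 2^(-t / halflife)`, a monotone saturating
#' curve of the kind seen in the evolutionary dynamics of growth and shape.
#'
#' Morphology vectors are named numerics with elements `meanL`, `meanW`
#' (micrometres) and `cvL`, `cvW` (lognormal coefficients of variation).
#'
#' Daily transfers use three candidate dilution factors; when
#' `adaptiveDilution` is `TRUE` (default) the three factors bracket the
#' regrowth predicted from the previous day's growth rate, mirroring a
#' protocol in which dilution rates are estimated from the daily growth
#' rate. The culture whose end-of-day density is within the exponential
#' phase and closest to `exponentialTarget` is selected for the next day;
#' post-dilution densities below `driftFloor` (default 1e4 cells/mL, the
#' genetic drift floor) are never used.
#'
#' @slot nLineages integer, lineages per arm (6, as in the experiment).
#' @slot nTransfers integer, number of daily transfers.
#' @slot carbonSource `"oleate_vesicle"` or `"glucose"`.
#' @slot carbonmM supplied carbon concentration, mM.
#' @slot dilutionOptions three positive dilution factors (used verbatim when
#'   `adaptiveDilution` is `FALSE`).
#' @slot adaptiveDilution logical; pick daily factors from predicted regrowth.
#' @slot exponentialTarget cells/mL defining "within the exponential phase".
#' @slot stationaryDensity cells/mL, carrying capacity of the daily culture.
#' @slot driftFloor cells/mL, minimum admissible post-dilution density.
#' @slot morphologyStart,morphologyTarget named numerics
#'   (`meanL`, `meanW`, `cvL`, `cvW`).
#' @slot fitnessStart,fitnessTarget growth rate, per hour.
#' @slot trajectoryHalflife transfers.
#' @slot gfpStart,gfpTarget GFP concentration, a.u. per cubic micrometre.
#' @slot gfpCv lognormal CV of per-cell GFP concentration.
#' @slot contaminantFractions named numerics `bead`, `debris`, `outOfFocus`,
#'   each in `[0, 1)`, summing to less than 1.
#' @slot pixelArea square micrometres per pixel (0.09, i.e. 0.3 um pixel side).
#' @slot noiseCv multiplicative intensity noise CV of rendered images.
#' @slot focusBlurSigma defocus blur (pixels) of out-of-focus events.
#' @slot measurementNoiseCv CV of day-level growth-rate measurement noise.
#' @slot rngSeed integer seed recorded with the configuration.
#'
#' @seealso [simulateLineageTrajectory()], [samplePopulation()], [runPipeline()]
#' @export
setClass("SimulationConfig",
  representation(
    nLineages = "integer", nTransfers = "integer",
    carbonSource = "character", carbonmM = "numeric",
    dilutionOptions = "numeric", adaptiveDilution = "logical",
    exponentialTarget = "numeric", stationaryDensity = "numeric",
    driftFloor = "numeric",
    morphologyStart = "numeric", morphologyTarget = "numeric",
    fitnessStart = "numeric", fitnessTarget = "numeric",
    trajectoryHalflife = "numeric",
    gfpStart = "numeric", gfpTarget = "numeric", gfpCv = "numeric",
    contaminantFractions = "numeric",
    pixelArea = "numeric", noiseCv = "numeric", focusBlurSigma = "numeric",
    measurementNoiseCv = "numeric",
    rngSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  morphNames <- c("meanL", "meanW", "cvL", "cvW")
  if (!all(morphNames %in% names(object@morphologyStart)) ||
      !all(morphNames %in% names(object@morphologyTarget)))
    msg <- c(msg, "morphology vectors need elements meanL, meanW, cvL, cvW")
  pos <- c(object@carbonmM, object@exponentialTarget, object@stationaryDensity,
           object@driftFloor, object@fitnessStart, object@fitnessTarget,
           object@trajectoryHalflife, object@gfpStart, object@gfpTarget,
           object@pixelArea)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "concentrations, rates, densities and half-life must be > 0")
  if (length(object@dilutionOptions) != 3L || any(object@dilutionOptions <= 0))
    msg <- c(msg, "dilutionOptions must be three positive factors")
  cf <- object@contaminantFractions
  if (!all(c("bead", "debris", "outOfFocus") %in% names(cf)))
    msg <- c(msg, "contaminantFractions needs elements bead, debris, outOfFocus")
  else if (any(cf < 0) || any(cf >= 1) || sum(cf) >= 1)
    msg <- c(msg, "contaminant fractions must lie in [0, 1) and sum to < 1")
  if (object@nLineages < 1L || object@nTransfers < 1L)
    msg <- c(msg, "need at least one lineage and one transfer")
  ms <- object@morphologyStart; mt <- object@morphologyTarget
  if (all(morphNames %in% names(ms)) && all(morphNames %in% names(mt)) &&
      (any(c(ms[morphNames][1:2], mt[morphNames][1:2]) <= 0) ||
       ms["meanW"] > ms["meanL"] || mt["meanW"] > mt["meanL"]))
    msg <- c(msg, "mean cell dimensions must be positive with meanW <= meanL")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Constructor; defaults describe the
#'   oleic-acid-vesicle arm of the experiment (6 lineages, 100 daily
#'   transfers at 3.5 mM OAV, rod ancestor of 3.0 x 1.0 um evolving toward
#'   1.5 x 1.0 um, growth rate 0.10 -> 0.16 per hour).
#'
#' @param carbonSource,carbonmM,nLineages,nTransfers,fitnessStart,fitnessTarget
#'   see slots.
#' @param morphologyStart,morphologyTarget,gfpStart,gfpTarget see slots.
#' @param ... remaining slots by name.
#' @export
SimulationConfig <- function(carbonSource = c("oleate_vesicle", "glucose"),
                             carbonmM = 3.5,
                             nLineages = 6L, nTransfers = 100L,
                             morphologyStart = c(meanL = 3.0, meanW = 1.0,
                                                 cvL = 0.15, cvW = 0.15),
                             morphologyTarget = c(meanL = 1.5, meanW = 1.0,
                                                  cvL = 0.15, cvW = 0.15),
                             fitnessStart = 0.10, fitnessTarget = 0.16,
                             gfpStart = 100, gfpTarget = 60,
                             ...) {
  carbonSource <- match.arg(carbonSource)
  dots <- list(...)
  defaults <- list(
    dilutionOptions = c(30, 100, 300), adaptiveDilution = TRUE,
    exponentialTarget = 1e7, stationaryDensity = 1e8, driftFloor = 1e4,
    trajectoryHalflife = 25, gfpCv = 0.2,
    contaminantFractions = c(bead = 0.05, debris = 0.05, outOfFocus = 0.10),
    pixelArea = 0.09, noiseCv = 0.05, focusBlurSigma = 2,
    measurementNoiseCv = 0.05, rngSeed = 1L)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown SimulationConfig parameters: ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(defaults, dots)
  new("SimulationConfig",
      nLineages = as.integer(nLineages), nTransfers = as.integer(nTransfers),
      carbonSource = carbonSource, carbonmM = carbonmM,
      dilutionOptions = args$dilutionOptions,
      adaptiveDilution = args$adaptiveDilution,
      exponentialTarget = args$exponentialTarget,
      stationaryDensity = args$stationaryDensity,
      driftFloor = args$driftFloor,
      morphologyStart = morphologyStart, morphologyTarget = morphologyTarget,
      fitnessStart = fitnessStart, fitnessTarget = fitnessTarget,
      trajectoryHalflife = args$trajectoryHalflife,
      gfpStart = gfpStart, gfpTarget = gfpTarget, gfpCv = args$gfpCv,
      contaminantFractions = args$contaminantFractions,
      pixelArea = args$pixelArea, noiseCv = args$noiseCv,
      focusBlurSigma = args$focusBlurSigma,
      measurementNoiseCv = args$measurementNoiseCv,
      rngSeed = as.integer(args$rngSeed))
}

#' Glucose-arm configuration
#'
#' Companion constructor for the glucose control arm: same protocol, higher
#' growth rates (0.18 -> 0.28 per hour), no programmed shape change, GFP
#' concentration drifting up rather than down.
#'
#' @param ... passed to [SimulationConfig()].
#' @export
glucoseConfig <- function(...) {
  SimulationConfig(carbonSource = "glucose", carbonmM = 10.5,
                   morphologyTarget = c(meanL = 3.0, meanW = 1.0,
                                        cvL = 0.15, cvW = 0.15),
                   fitnessStart = 0.18, fitnessTarget = 0.28,
                   gfpStart = 100, gfpTarget = 130, ...)
}

#' CellImage: one imaging-flow-cytometer event
#'
#' Two-channel pixel grid for a single acquired event: a fluorescence channel
#' and a brightfield-like support ("mask proxy") channel, with the calibrated
#' pixel area. Simulated events carry a ground-truth label (`cell`, `bead`,
#' `debris`), a focus flag and the true generating parameters, which the
#' gating and morphometry stages never look at -- they exist so tests can
#' score the pipeline against the truth.
#'
#' @slot fluor numeric matrix, fluorescence intensities (a.u., >= 0).
#' @slot mask numeric matrix, support-proxy channel (same dimensions).
#' @slot pixelArea square micrometres per pixel.
#' @slot label `"cell"`, `"bead"` or `"debris"`.
#' @slot inFocus logical focus flag (ground truth).
#' @slot truth list of generating parameters (simulator only; may be empty).
#' @export
setClass("CellImage",
  representation(fluor = "matrix", mask = "matrix", pixelArea = "numeric",
                 label = "character", inFocus = "logical", truth = "list"))

setValidity("CellImage", function(object) {
  msg <- character()
  if (!all(dim(object@fluor) == dim(object@mask)))
    msg <- c(msg, "fluor and mask channels must share dimensions")
  if (length(object@pixelArea) != 1L || object@pixelArea <= 0)
    msg <- c(msg, "pixelArea must be a single positive number")
  if (any(object@fluor < 0) || any(object@mask < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (!object@label %in% c("cell", "bead", "debris"))
    msg <- c(msg, "label must be cell, bead or debris")
  if (length(msg)) msg else TRUE
})

#' PopulationSample: gated or ungated event collection
#'
#' Events acquired for one lineage x transfer x condition, before or after
#' gating.
#'
#' @slot events list of [CellImage-class] objects.
#' @slot lineage character lineage id.
#' @slot transfer integer transfer index (0 = ancestor).
#' @slot condition character, carbon source of the arm.
#' @export
setClass("PopulationSample",
  representation(events = "list", lineage = "character",
                 transfer = "integer", condition = "character"))

setValidity("PopulationSample", function(object) {
  ok <- vapply(object@events, is, logical(1), class2 = "CellImage")
  if (!all(ok)) "all events must be CellImage objects" else TRUE
})

#' GateConfig: event-quality gate thresholds
#'
#' Thresholds for the three-stage event gating applied before morphometry:
#' a fluorescence-intensity gate (removes calibration beads and dim culture
#' debris), an aspect-ratio-intensity gate (removes irregular/elongated
#' non-cell objects), and a gradient-RMS sharpness gate (removes
#' out-of-focus events). Instrument software applies the same three gates
#' interactively; the defaults here were calibrated once against the
#' simulator's labelled default output and are expected to be overridden
#' per dataset.
#'
#' @slot fluorescenceMin minimum integrated fluorescence (a.u.).
#' @slot aspectIntensityBounds ordered `(low, high)` bounds on the aspect
#'   ratio of the intensity-weighted second-moment ellipse of the
#'   fluorescence channel.
#' @slot gradientRmsMin minimum gradient RMS (sharpness) of the normalized
#'   fluorescence channel.
#' @export
setClass("GateConfig",
  representation(fluorescenceMin = "numeric",
                 aspectIntensityBounds = "numeric",
                 gradientRmsMin = "numeric"))

setValidity("GateConfig", function(object) {
  msg <- character()
  if (length(object@aspectIntensityBounds) != 2L ||
      diff(object@aspectIntensityBounds) < 0)
    msg <- c(msg, "aspectIntensityBounds must be ordered (low, high)")
  if (object@fluorescenceMin < 0 || object@gradientRmsMin < 0 ||
      any(object@aspectIntensityBounds < 0))
    msg <- c(msg, "thresholds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn GateConfig-class Constructor with simulator-calibrated defaults.
#' @param fluorescenceMin,aspectIntensityBounds,gradientRmsMin see slots.
#' @export
GateConfig <- function(fluorescenceMin = 15,
                       aspectIntensityBounds = c(0.1, 1),
                       gradientRmsMin = 0.155) {
  new("GateConfig", fluorescenceMin = fluorescenceMin,
      aspectIntensityBounds = aspectIntensityBounds,
      gradientRmsMin = gradientRmsMin)
}

#' GrowthCurve: timestamped population-density series
#'
#' @slot times hours, strictly increasing.
#' @slot densities cells/mL (or OD-like a.u. when `od` is `TRUE`).
#' @slot carbonSource `"oleate_vesicle"` or `"glucose"`.
#' @slot carbonmM supplied carbon concentration, mM.
#' @slot replicate character replicate id.
#' @slot od logical; `TRUE` when densities are relative OD-like readings.
#' @export
setClass("GrowthCurve",
  representation(times = "numeric", densities = "numeric",
                 carbonSource = "character", carbonmM = "numeric",
                 replicate = "character", od = "logical"))

setValidity("GrowthCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@densities))
    msg <- c(msg, "times and densities must have equal length")
  if (length(object@times) && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@densities < 0))
    msg <- c(msg, "densities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn GrowthCurve-class Constructor.
#' @param times,densities,carbonSource,carbonmM,replicate,od see slots.
#' @export
GrowthCurve <- function(times, densities,
                        carbonSource = c("oleate_vesicle", "glucose"),
                        carbonmM = 3.5, replicate = "r1", od = FALSE) {
  new("GrowthCurve", times = as.numeric(times),
      densities = as.numeric(densities),
      carbonSource = match.arg(carbonSource), carbonmM = carbonmM,
      replicate = replicate, od = od)
}

#' LineageTrajectory: per-transfer measured summaries for one lineage
#'
#' Measured per-transfer series assembled from gated populations: growth
#' rate plus population means (and dispersions) of the morphometric
#' features used in the trajectory and correlation analyses.
#'
#' The `records` data.frame has one row per measured transfer with at least
#' the columns `transfer`, `generations`, `growthRate`, `meanAR`, `meanL`,
#' `meanW`, `meanLogA`, `meanLogV`, `meanAV`, `meanGFPperV`, `nEvents`.
#'
#' @slot lineage character id.
#' @slot condition character, carbon source of the arm.
#' @slot records data.frame as described above.
#' @export
setClass("LineageTrajectory",
  representation(lineage = "character", condition = "character",
                 records = "data.frame"))

setValidity("LineageTrajectory", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("transfer", "growthRate", "meanAR", "meanL", "meanW")
  if (!all(need %in% names(rec)))
    msg <- c(msg, paste("records needs columns:", paste(need, collapse = ", ")))
  if (nrow(rec) > 1 && any(diff(rec$transfer) <= 0))
    msg <- c(msg, "transfer indices must be strictly increasing")
  if ("nEvents" %in% names(rec) && any(rec$nEvents < 1))
    msg <- c(msg, "summaries must come from at least one gated event")
  if (length(msg)) msg else TRUE
})

#' @describeIn LineageTrajectory-class Constructor.
#' @param lineage,condition,records see slots.
#' @export
LineageTrajectory <- function(lineage, condition, records) {
  new("LineageTrajectory", lineage = as.character(lineage),
      condition = as.character(condition), records = records)
}

#' CorrelationMatrix: pairwise feature correlations with significance
#'
#' Symmetric Pearson (or Spearman) correlation matrix over trajectory-level
#' feature series, with two-sided p-values and the number of paired
#' observations. Pairs involving a constant feature are undefined: their
#' `r` is `NA` and their p-value 1.
#'
#' @slot features character feature names.
#' @slot r,p numeric matrices.
#' @slot n integer, paired observations per cell.
#' @slot method character, correlation type.
#' @export
setClass("CorrelationMatrix",
  representation(features = "character", r = "matrix", p = "matrix",
                 n = "integer", method = "character"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r; p <- object@p
  if (!all(dim(r) == length(object@features)) || !all(dim(p) == dim(r)))
    msg <- c(msg, "r and p must be square with one row per feature")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "|r| must be <= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  offd <- abs(r - t(r))
  if (any(offd > 1e-8, na.rm = TRUE))
    msg <- c(msg, "r must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal of r must be 1")
  if (length(msg)) msg else TRUE
})
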