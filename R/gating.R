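#' @include AllClasses.R
NULL

## bounding box (with margin) of the event support: pixels above 5% of the
## robust foreground level
eventBoundingBox <- function(m, margin = 2L) {
  mx <- max(m)
  if (mx <= 0) return(NULL)
  idx <- which(m > 0.05 * mx, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(r = max(1L, min(idx[, 1]) - margin):min(nrow(m), max(idx[, 1]) + margin),
       c = max(1L, min(idx[, 2]) - margin):min(ncol(m), max(idx[, 2]) + margin))
}

#' Gradient RMS image sharpness
#'
#' Root mean square of the finite-difference gradient magnitude of the
#' fluorescence channel, the sharpness score used to discard out-of-focus
#' events. The gradient uses central differences in the interior and
#' one-sided differences at the borders, with unit pixel spacing; the RMS
#' is taken over the event bounding box (support plus a 2-pixel margin).
#' The image is first normalized by its maximum intensity, so the score is
#' invariant to detector gain and expression level. A constant or
#' single-pixel image scores 0 by convention.
#'
#' @param image a [CellImage-class] or a numeric matrix.
#' @return scalar sharpness, a.u.
#' @examples
#' gradientRMS(matrix(c(0, 0, 1, 1), 2, 2))
#' @export
gradientRMS <- function(image) {
  m <- if (is(image, "CellImage")) image@fluor else as.matrix(image)
  if (length(m) <= 1L) return(0)
  bb <- eventBoundingBox(m)
  if (is.null(bb)) return(0)
  m <- m[bb$r, bb$c, drop = FALSE]
  sc <- max(m)
  if (sc <= 0) return(0)
  m <- m / sc
  n <- nrow(m); p <- ncol(m)
  gi <- m * 0
  if (n > 1) {
    gi[1, ] <- m[2, ] - m[1, ]
    gi[n, ] <- m[n, ] - m[n - 1, ]
    if (n > 2) gi[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  }
  gj <- m * 0
  if (p > 1) {
    gj[, 1] <- m[, 2] - m[, 1]
    gj[, p] <- m[, p] - m[, p - 1]
    if (p > 2) gj[, 2:(p - 1)] <- (m[, 3:p] - m[, 1:(p - 2)]) / 2
  }
  sqrt(mean(gi^2 + gj^2))
}

#' Aspect ratio intensity
#'
#' Aspect ratio of the intensity-weighted second-moment ellipse of the
#' fluorescence channel: the square root of the ratio of the smaller to the
#' larger eigenvalue of the intensity-weighted covariance of pixel
#' coordinates. Lies in (0, 1]; 1 for radially symmetric events. This is
#' the fluorescence-weighted shape score used (together with intensity) to
#' exclude beads and debris before morphometry.
#'
#' @param image a [CellImage-class] or numeric matrix.
#' @return scalar in (0, 1], or `NA` for an empty image.
#' @export
aspectRatioIntensity <- function(image) {
  m <- if (is(image, "CellImage")) image@fluor else as.matrix(image)
  w <- pmax(m, 0)
  s <- sum(w)
  if (s <= 0) return(NA_real_)
  n <- nrow(m); p <- ncol(m)
  X <- matrix(seq_len(n), n, p)
  Y <- matrix(seq_len(p), n, p, byrow = TRUE)
  cx <- sum(X * w) / s; cy <- sum(Y * w) / s
  vx <- sum((X - cx)^2 * w) / s
  vy <- sum((Y - cy)^2 * w) / s
  vxy <- sum((X - cx) * (Y - cy) * w) / s
  ev <- eigen(matrix(c(vx, vxy, vxy, vy), 2), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 1e-12)
  sqrt(ev[2] / ev[1])
}

#' Gate events before morphometry
#'
#' Applies the three event-quality gates in order: (1) fluorescence
#' intensity (removes calibration beads and dim culture debris), (2)
#' aspect-ratio intensity (removes irregular or extremely elongated
#' non-cell objects), (3) gradient RMS (removes out-of-focus events). Each
#' event is tested against the first gate it fails; the report counts
#' removals per gate. Gating is idempotent and always returns a subset of
#' the input.
#'
#' @param x a [PopulationSample-class] or list of [CellImage-class] events.
#' @param config a [GateConfig-class]; defaults are simulator-calibrated.
#' @return list with elements `sample` (gated input, same class) and
#'   `report` (data.frame: gate, removed, retained).
#' @examples
#' pop <- samplePopulation(list(trueL = 3, trueW = 1, trueGfp = 100),
#'                         nEvents = 50)
#' g <- gateEvents(pop)
#' g$report
#' @export
gateEvents <- function(x, config = GateConfig()) {
  stopifnot(is(config, "GateConfig"))
  validObject(config)
  evs <- if (is(x, "PopulationSample")) x@events else x
  nIn <- length(evs)
  if (!nIn) {
    report <- data.frame(gate = c("fluorescence", "aspect_intensity",
                                  "gradient_rms"),
                         removed = c(0L, 0L, 0L), retained = c(0L, 0L, 0L))
    return(list(sample = x, report = report))
  }
  total <- vapply(evs, function(e) sum(e@fluor), numeric(1))
  keep1 <- total >= config@fluorescenceMin
  ari <- rep(NA_real_, nIn)
  ari[keep1] <- vapply(evs[keep1], aspectRatioIntensity, numeric(1))
  b <- config@aspectIntensityBounds
  keep2 <- keep1 & !is.na(ari) & ari >= b[1] & ari <= b[2]
  grms <- rep(NA_real_, nIn)
  grms[keep2] <- vapply(evs[keep2], gradientRMS, numeric(1))
  keep3 <- keep2 & grms >= config@gradientRmsMin
  report <- data.frame(
    gate = c("fluorescence", "aspect_intensity", "gradient_rms"),
    removed = c(sum(!keep1), sum(keep1 & !keep2), sum(keep2 & !keep3)),
    retained = c(sum(keep1), sum(keep2), sum(keep3)))
  if (!any(keep3))
    warning("all events removed by gating")
  out <- if (is(x, "PopulationSample")) {
    new("PopulationSample", events = evs[keep3], lineage = x@lineage,
        transfer = x@transfer, condition = x@condition)
  } else evs[keep3]
  list(sample = out, report = report)
}
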