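#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @aliases fluorChannel,CellImage-method
setMethod("fluorChannel", "CellImage", function(object) object@fluor)

#' @rdname accessors
setMethod("maskChannel", "CellImage", function(object) object@mask)

#' @rdname accessors
setMethod("pixelArea", "CellImage", function(object) object@pixelArea)

#' @rdname accessors
setMethod("eventLabel", "CellImage", function(object) object@label)

#' @rdname accessors
setMethod("inFocus", "CellImage", function(object) object@inFocus)

#' @rdname accessors
setMethod("groundTruth", "CellImage", function(object) object@truth)

#' @rdname accessors
setMethod("events", "PopulationSample", function(object) object@events)

#' @rdname accessors
setMethod("lineage", "PopulationSample", function(object) object@lineage)

#' @rdname accessors
setMethod("condition", "PopulationSample", function(object) object@condition)

#' @rdname accessors
setMethod("lineage", "LineageTrajectory", function(object) object@lineage)

#' @rdname accessors
setMethod("condition", "LineageTrajectory", function(object) object@condition)

#' @rdname accessors
setMethod("records", "LineageTrajectory", function(object) object@records)

#' @rdname accessors
setMethod("curveTimes", "GrowthCurve", function(object) object@times)

#' @rdname accessors
setMethod("densities", "GrowthCurve", function(object) object@densities)

#' @rdname accessors
setMethod("carbonSource", "GrowthCurve", function(object) object@carbonSource)

#' @rdname accessors
setMethod("carbonConc", "GrowthCurve", function(object) object@carbonmM)

#' Number of events in a sample
#' @param x a [PopulationSample-class].
#' @export
setMethod("length", "PopulationSample", function(x) length(x@events))

setMethod("show", "CellImage", function(object) {
  d <- dim(object@fluor)
  cat(sprintf("CellImage %dx%d px (%.2f um2/px), label=%s, %s\n",
              d[1], d[2], object@pixelArea, object@label,
              if (object@inFocus) "in focus" else "out of focus"))
})

setMethod("show", "PopulationSample", function(object) {
  labs <- vapply(object@events, function(e) e@label, character(1))
  cat(sprintf("PopulationSample: lineage %s, transfer %d (%s)\n",
              object@lineage, object@transfer, object@condition))
  cat("  events:", length(object@events),
      sprintf("(%d cell, %d bead, %d debris)\n",
              sum(labs == "cell"), sum(labs == "bead"), sum(labs == "debris")))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d lineages x %d transfers on %s (%.3g mM)\n",
              object@nLineages, object@nTransfers, object@carbonSource,
              object@carbonmM))
  cat(sprintf("  growth rate %.3g -> %.3g /h, half-life %.3g transfers\n",
              object@fitnessStart, object@fitnessTarget,
              object@trajectoryHalflife))
  cat(sprintf("  morphology L %.2f -> %.2f um, W %.2f -> %.2f um\n",
              object@morphologyStart["meanL"], object@morphologyTarget["meanL"],
              object@morphologyStart["meanW"], object@morphologyTarget["meanW"]))
  cat(sprintf("  GFP %.3g -> %.3g a.u./um3; contaminants %s\n",
              object@gfpStart, object@gfpTarget,
              paste(sprintf("%s=%.2g", names(object@contaminantFractions),
                            object@contaminantFractions), collapse = " ")))
})

setMethod("show", "GateConfig", function(object) {
  cat(sprintf(
    "GateConfig: fluorescence >= %.3g; aspect intensity in [%.3g, %.3g]; gradient RMS >= %.3g\n",
    object@fluorescenceMin, object@aspectIntensityBounds[1],
    object@aspectIntensityBounds[2], object@gradientRmsMin))
})

setMethod("show", "GrowthCurve", function(object) {
  cat(sprintf("GrowthCurve (%s, %.3g mM, replicate %s): %d points, %.1f-%.1f h%s\n",
              object@carbonSource, object@carbonmM, object@replicate,
              length(object@times),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA,
              if (object@od) " [OD mode]" else ""))
})

setMethod("show", "LineageTrajectory", function(object) {
  rec <- object@records
  cat(sprintf("LineageTrajectory %s (%s): %d measured transfers\n",
              object@lineage, object@condition, nrow(rec)))
  if (nrow(rec)) {
    first <- rec[1, ]; last <- rec[nrow(rec), ]
    cat(sprintf("  growth rate %.3g -> %.3g /h; mean AR %.3g -> %.3g\n",
                first$growthRate, last$growthRate, first$meanAR, last$meanAR))
  }
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix (%s, n = %d) over %s\n", object@method,
              object@n, paste(object@features, collapse = ", ")))
  r <- round(object@r, 2)
  print(r)
})
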