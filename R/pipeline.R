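#' @include AllClasses.R simulate.R gating.R morphometry.R growth.R evodynamics.R stats_report.R io.R
NULL

## per-lineage biological variability: scale the programmed evolutionary
## effects (target minus start) and the relaxation half-life by a lognormal
## factor, so independent lineages differ in the magnitude of their response
## but an arm with no programmed change stays trend-free
perturbConfig <- function(config, cv = 0.08) {
  jit <- function(c = cv) stats::rlnorm(1, -log(1 + c^2) / 2,
                                        sqrt(log(1 + c^2)))
  scaleEffect <- function(start, target) start + (target - start) * jit()
  mt <- config@morphologyTarget
  mt["meanL"] <- max(scaleEffect(config@morphologyStart[["meanL"]],
                                 mt[["meanL"]]), mt[["meanW"]])
  config@morphologyTarget <- mt
  config@fitnessTarget <- scaleEffect(config@fitnessStart,
                                      config@fitnessTarget)
  config@gfpTarget <- scaleEffect(config@gfpStart, config@gfpTarget)
  config@trajectoryHalflife <- config@trajectoryHalflife * jit(2 * cv)
  config
}

## population summary of a gated feature table
summarizeFeatures <- function(ft) {
  data.frame(
    meanAR = mean(ft$AR), sdAR = stats::sd(ft$AR),
    meanL = mean(ft$L), sdL = stats::sd(ft$L),
    meanW = mean(ft$W), sdW = stats::sd(ft$W),
    meanLogA = mean(log10(ft$A)), meanLogV = mean(log10(ft$V)),
    meanAV = mean(ft$AV), sdAV = stats::sd(ft$AV),
    meanGFPperV = mean(ft$GFP_per_V), sdGFPperV = stats::sd(ft$GFP_per_V),
    nEvents = nrow(ft))
}

#' Measure one lineage: images to trajectory
#'
#' Runs the single-lineage measurement chain of the pipeline: for each
#' measured transfer, sample an imaged population from the ground truth,
#' gate it, extract features, and summarize into one trajectory record.
#' The measured growth rate is the realized daily rate
#' `ln(nEnd/n0) / 24 h` of the selected culture with multiplicative
#' measurement noise.
#'
#' @param truth ground-truth table from [simulateLineageTrajectory()].
#' @param config the [SimulationConfig-class] that produced it.
#' @param gate a [GateConfig-class].
#' @param eventsPerTransfer events to acquire per measured transfer.
#' @param measureEvery measure every k-th transfer (plus origin and
#'   endpoint).
#' @param method axis estimator, see [extractAxes()].
#' @return list with `trajectory` (a [LineageTrajectory-class]) and
#'   `gateReport` (summed removal counts).
#' @export
measureLineage <- function(truth, config, gate = GateConfig(),
                           eventsPerTransfer = 120L, measureEvery = 5L,
                           method = "capsule") {
  nT <- max(truth$transfer)
  ts <- sort(unique(c(seq(0L, nT, by = measureEvery), nT)))
  gateTotal <- NULL
  rows <- vector("list", length(ts))
  for (k in seq_along(ts)) {
    t <- ts[k]
    row <- truth[truth$transfer == t, ]
    pop <- samplePopulation(
      row, nEvents = eventsPerTransfer,
      contaminantFractions = config@contaminantFractions,
      cvL = config@morphologyStart[["cvL"]],
      cvW = config@morphologyStart[["cvW"]],
      gfpCv = config@gfpCv, pixelArea = config@pixelArea,
      noiseCv = config@noiseCv, focusBlurSigma = config@focusBlurSigma,
      lineage = row$lineage, transfer = t, condition = config@carbonSource)
    g <- gateEvents(pop, gate)
    ft <- populationFeatures(g$sample, method = method)
    if (!nrow(ft)) stop("no events survived gating at transfer ", t)
    gateTotal <- if (is.null(gateTotal)) g$report else {
      gr <- g$report; gr$removed <- gr$removed + gateTotal$removed
      gr$retained <- gr$retained + gateTotal$retained; gr
    }
    muDay <- if (t == 0) row$trueMu else log(row$nEnd / row$n0) / 24
    muMeas <- muDay * (1 + stats::rnorm(1, 0, config@measurementNoiseCv))
    rows[[k]] <- cbind(
      data.frame(transfer = t, generations = row$generations,
                 growthRate = muMeas),
      summarizeFeatures(ft))
  }
  rec <- do.call(rbind, rows)
  list(trajectory = LineageTrajectory(truth$lineage[1], config@carbonSource,
                                      rec),
       gateReport = gateTotal)
}

## resource-utilization assay defaults: growth rates and carrying capacities
## (cells/mL per substrate mM) for the ancestor and the evolved strains in
## each carbon source; the programmed trade-off is capacity up in oleate
## vesicles, down in glucose, for the evolved strains
resourceDefaults <- function() {
  list(
    concentrations = list(oleate_vesicle = c(0.035, 0.07, 0.35, 0.7, 3.5),
                          glucose = c(0.105, 0.21, 1.05, 2.1, 10.5)),
    mu = list(oleate_vesicle = c(Ori = 0.10, Evo = 0.16),
              glucose = c(Ori = 0.18, Evo = 0.22)),
    capacityPerMM = list(oleate_vesicle = c(Ori = 2.5e7, Evo = 3.3e7),
                         glucose = c(Ori = 9.5e6, Evo = 7.0e6)))
}

## simulate and analyse the resource-utilization assay for Ori and Evo in
## both carbon sources; nReps replicate curves per concentration
runResourceAssay <- function(nReps = 6L, noiseCv = 0.05,
                             defaults = resourceDefaults()) {
  rows <- list()
  for (src in names(defaults$concentrations)) {
    for (strain in c("Ori", "Evo")) {
      for (conc in defaults$concentrations[[src]]) {
        K <- defaults$capacityPerMM[[src]][[strain]] * conc
        inoc <- min(1e5, K / 50)
        ## sample until well past stationary onset for the slowest strain
        for (r in seq_len(nReps)) {
          cv <- simulateGrowthCurve(defaults$mu[[src]][[strain]], inoc, K,
                                    times = seq(0, 96, by = 3),
                                    noiseCv = noiseCv, carbonSource = src,
                                    carbonmM = conc,
                                    replicate = paste0(strain, "_r", r))
          cap <- carryingCapacity(cv)
          fit <- fitGrowthRate(cv)
          rows[[length(rows) + 1L]] <- data.frame(
            source = src, strain = strain, mM = conc,
            carbonEquivmM = normalizeCarbon(conc, src),
            mu = fit$mu, capacity = cap$capacity,
            maxDensity = cap$maxDensity, replicate = r)
        }
      }
    }
  }
  caps <- do.call(rbind, rows)
  ## cubic capacity trend per strain x source over log concentration
  trends <- list()
  tradeoff <- list()
  for (src in unique(caps$source)) {
    for (strain in c("Ori", "Evo")) {
      sub <- caps[caps$source == src & caps$strain == strain, ]
      trends[[paste(src, strain, sep = ".")]] <-
        fitCapacityTrend(sub$mM, sub$capacity)
    }
    ori <- caps[caps$source == src & caps$strain == "Ori", "capacity"]
    evo <- caps[caps$source == src & caps$strain == "Evo", "capacity"]
    tradeoff[[src]] <- compareGroups(evo, ori)
  }
  list(capacities = caps, trends = trends, tradeoff = tradeoff)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' End-to-end orchestration: simulate both evolution arms (six lineages
#' each by default), image and gate populations at the measured transfers,
#' extract features, assemble trajectories, and run the downstream
#' analyses -- logarithmic trend fits, endpoint/origin fold changes with
#' the cross-arm permutation comparison, per-lineage feature correlations,
#' ancestor-versus-evolved area-to-volume and GFP-concentration contrasts,
#' and the resource-utilization assay with its capacity trade-off tests.
#'
#' All randomness is derived from `seed`; per-lineage sub-seeds are drawn
#' up front and recorded in the manifest, so any lineage can be re-measured
#' in isolation. Rerunning with the same seed reproduces every output
#' exactly.
#'
#' @param oavConfig,glcConfig [SimulationConfig-class] objects for the two
#'   arms.
#' @param seed integer seed.
#' @param eventsPerTransfer,measureEvery,gate,method see [measureLineage()].
#' @param lineageCv CV of the per-lineage jitter applied to evolved targets.
#' @param resourceReps replicate growth curves per concentration in the
#'   resource assay (0 skips the assay).
#' @param outDir optional directory; when given, all numeric tables are
#'   written there as TSV together with a run manifest.
#' @return list with elements `trajectories` (per arm), `trends`, `folds`,
#'   `foldTests`, `correlations`, `avComparison`, `gfpComparison`,
#'   `resource`, `gateReport`, `manifest`.
#' @export
runPipeline <- function(oavConfig = SimulationConfig(),
                        glcConfig = glucoseConfig(),
                        seed = 1L, eventsPerTransfer = 120L,
                        measureEvery = 5L, gate = GateConfig(),
                        method = "capsule", lineageCv = 0.08,
                        resourceReps = 6L, outDir = NULL) {
  set.seed(seed)
  arms <- list(oleate_vesicle = oavConfig, glucose = glcConfig)
  prefixes <- c(oleate_vesicle = "L", glucose = "G")
  ids <- c("31", "32", "9", "10", "11", "12")   # lineage labels per arm
  nLin <- vapply(arms, function(a) a@nLineages, integer(1))
  subSeeds <- matrix(sample.int(.Machine$integer.max - 1L, sum(nLin)),
                     nrow = max(nLin))
  trajectories <- list()
  truths <- list()
  gateReport <- NULL
  for (ai in seq_along(arms)) {
    arm <- names(arms)[ai]
    cfg <- arms[[ai]]
    trs <- vector("list", cfg@nLineages)
    tru <- vector("list", cfg@nLineages)
    for (li in seq_len(cfg@nLineages)) {
      set.seed(subSeeds[li, ai])
      cfgL <- perturbConfig(cfg, cv = lineageCv)
      id <- paste0(prefixes[[arm]],
                   if (li <= length(ids)) ids[li] else as.character(li))
      truth <- simulateLineageTrajectory(cfgL, lineageId = id)
      m <- measureLineage(truth, cfgL, gate = gate,
                          eventsPerTransfer = eventsPerTransfer,
                          measureEvery = measureEvery, method = method)
      trs[[li]] <- m$trajectory
      tru[[li]] <- truth
      gateReport <- if (is.null(gateReport)) m$gateReport else {
        gr <- m$gateReport
        gr$removed <- gr$removed + gateReport$removed
        gr$retained <- gr$retained + gateReport$retained
        gr
      }
    }
    trajectories[[arm]] <- trs
    truths[[arm]] <- tru
  }

  ## logarithmic trends of growth rate and aspect ratio per lineage
  trends <- do.call(rbind, lapply(unlist(trajectories), function(tr) {
    rec <- tr@records
    if (nrow(rec) < 3L) return(NULL)
    do.call(rbind, lapply(c("growthRate", "meanAR"), function(f) {
      ft <- fitLogTrend(rec$transfer, rec[[f]])
      data.frame(lineage = tr@lineage, condition = tr@condition, feature = f,
                 a = ft$a, b = ft$b, r2 = ft$r2)
    }))
  }))

  ## endpoint/origin fold changes and the cross-arm comparisons
  folds <- do.call(rbind, lapply(c("growthRate", "meanAR", "meanL", "meanAV"),
    function(f) rbind(foldChanges(trajectories$oleate_vesicle, f),
                      foldChanges(trajectories$glucose, f))))
  foldTests <- lapply(stats::setNames(nm = c("growthRate", "meanAR")),
    function(f) {
      sub <- folds[folds$feature == f, ]
      tryCatch(
        compareFoldChangeGroups(sub$fold[sub$condition == "oleate_vesicle"],
                                sub$fold[sub$condition == "glucose"]),
        error = function(e) NULL)
    })

  ## per-lineage six-feature correlation matrices (need >= 4 records)
  correlations <- lapply(trajectories, function(trs)
    lapply(trs, function(tr)
      tryCatch(featureCorrelations(tr), error = function(e) NULL)))

  ## ancestor-versus-evolved contrasts in the oleate-vesicle arm
  oavLong <- trajectoriesToLong(trajectories$oleate_vesicle)
  origin <- oavLong[oavLong$transfer == 0, ]
  endpoint <- oavLong[oavLong$transfer == max(oavLong$transfer), ]
  avComparison <- tryCatch(compareGroups(endpoint$meanAV, origin$meanAV),
                           error = function(e) NULL)
  gfpComparison <- tryCatch(
    compareGroups(endpoint$meanGFPperV, origin$meanGFPperV),
    error = function(e) NULL)

  resource <- if (resourceReps > 0) runResourceAssay(nReps = resourceReps)
              else NULL

  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("evomorph")),
                   subSeeds = subSeeds,
                   lineages = vapply(unlist(trajectories),
                                     function(tr) tr@lineage, character(1)),
                   eventsPerTransfer = eventsPerTransfer,
                   measureEvery = measureEvery,
                   nLineages = nLin)
  out <- list(trajectories = trajectories, truths = truths, trends = trends,
              folds = folds, foldTests = foldTests,
              correlations = correlations, avComparison = avComparison,
              gfpComparison = gfpComparison, resource = resource,
              gateReport = gateReport, manifest = manifest)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

## write the pipeline's numeric tables (TSV interchange dialect) plus a
## small manifest
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeTSV(do.call(rbind, c(res$truths$oleate_vesicle, res$truths$glucose)),
           p("ground_truth.tsv"))
  writeTSV(trajectoriesToLong(c(res$trajectories$oleate_vesicle,
                                res$trajectories$glucose)),
           p("trajectories.tsv"))
  if (!is.null(res$trends)) writeTSV(res$trends, p("log_trends.tsv"))
  writeTSV(res$folds, p("fold_changes.tsv"))
  ft <- do.call(rbind, lapply(names(res$foldTests), function(f) {
    x <- res$foldTests[[f]]
    if (is.null(x)) return(NULL)
    data.frame(feature = f, meanDiff = x$statistic, p_perm = x$p,
               exact = x$exact, welch_t = x$welch_t, welch_p = x$welch_p)
  }))
  if (!is.null(ft)) writeTSV(ft, p("fold_tests.tsv"))
  corLong <- do.call(rbind, lapply(names(res$correlations), function(arm) {
    do.call(rbind, lapply(res$correlations[[arm]], function(cm) {
      if (is.null(cm)) return(NULL)
      ij <- which(upper.tri(cm@r), arr.ind = TRUE)
      data.frame(condition = arm,
                 feature_i = cm@features[ij[, 1]],
                 feature_j = cm@features[ij[, 2]],
                 r = cm@r[ij], p = cm@p[ij], n = cm@n)
    }))
  }))
  if (!is.null(corLong)) writeTSV(corLong, p("correlations.tsv"))
  writeTSV(res$gateReport, p("gate_report.tsv"))
  if (!is.null(res$resource))
    writeTSV(res$resource$capacities, p("capacities.tsv"))
  mf <- res$manifest
  writeTSV(data.frame(key = c("seed", "version", "eventsPerTransfer",
                              "measureEvery", "lineages"),
                      value = c(mf$seed, mf$version, mf$eventsPerTransfer,
                                mf$measureEvery,
                                paste(mf$lineages, collapse = ","))),
           p("manifest.tsv"))
  invisible(outDir)
}
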