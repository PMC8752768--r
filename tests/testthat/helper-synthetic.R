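## shared fixtures and independent oracles, built in code at test time

## a noiseless rendered cell with reproducible subpixel phase
noiselessCell <- function(L, W, theta = 0.4, phase = c(0.2, -0.3), ...) {
  renderCellImage(L, W, orientation = theta, noiseCv = 0,
                  backgroundNoise = 0, phase = phase, ...)
}

defaultTruth <- list(trueL = 3, trueW = 1, trueGfp = 100)

## independent brute-force oracle for the two-sided permutation test on the
## difference of group means: explicit loop over every split
enumPermOracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(length(pool), na)
  hits <- 0L
  for (k in seq_len(ncol(splits))) {
    ga <- pool[splits[, k]]
    gb <- pool[-splits[, k]]
    if (abs(mean(ga) - mean(gb)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(splits)
}

## one shared scaled-down end-to-end run, computed lazily and cached for the
## acceptance tests (12 lineages, 60 transfers measured every 6, 80 events
## per measured transfer)
.pipelineCache <- new.env(parent = emptyenv())
acceptanceRun <- function() {
  if (is.null(.pipelineCache$res)) {
    .pipelineCache$res <- runPipeline(
      oavConfig = SimulationConfig(nTransfers = 60L),
      glcConfig = glucoseConfig(nTransfers = 60L),
      seed = 101L, eventsPerTransfer = 80L, measureEvery = 6L,
      resourceReps = 6L)
  }
  .pipelineCache$res
}
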