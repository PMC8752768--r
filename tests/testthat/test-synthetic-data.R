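test_that("degenerate no-evolution config yields identical true parameters", {
  cfg <- SimulationConfig(nTransfers = 12L,
                          morphologyTarget = c(meanL = 3, meanW = 1,
                                               cvL = 0.15, cvW = 0.15),
                          fitnessTarget = 0.10, gfpTarget = 100)
  tr <- simulateLineageTrajectory(cfg)
  expect_equal(length(unique(tr$trueL)), 1L)
  expect_equal(length(unique(tr$trueMu)), 1L)
  expect_equal(length(unique(tr$trueGfp)), 1L)
})

test_that("generation accounting: 1000-fold daily dilution gives ~9.97 generations/day", {
  ## growth exactly balances the dilution: exp(24 mu) = 1000
  mu <- log(1000) / 24
  cfg <- SimulationConfig(nTransfers = 50L,
                          fitnessStart = mu, fitnessTarget = mu,
                          morphologyTarget = c(meanL = 3, meanW = 1,
                                               cvL = 0.15, cvW = 0.15),
                          dilutionOptions = c(1000, 1000, 1000),
                          adaptiveDilution = FALSE,
                          stationaryDensity = 1e12, driftFloor = 1e3)
  tr <- simulateLineageTrajectory(cfg)
  expect_equal(tr$dailyGenerations[2], log2(1000), tolerance = 1e-3)
  ## ~50 transfers reach ~500 generations
  expect_equal(tail(tr$generations, 1), 50 * log2(1000), tolerance = 0.01)
  ## cumulative generations equal the sum of daily log2 regrowth folds exactly
  expect_equal(tr$generations,
               cumsum(ifelse(is.na(tr$n0), 0, log2(tr$nEnd / tr$n0))),
               tolerance = 1e-12)
  expect_true(all(diff(tr$generations) >= 0))
})

test_that("simulator is deterministic under a fixed seed", {
  cfg <- SimulationConfig(nTransfers = 8L)
  t1 <- simulateLineageTrajectory(cfg)
  t2 <- simulateLineageTrajectory(cfg)
  expect_identical(t1, t2)
  set.seed(33); p1 <- samplePopulation(defaultTruth, nEvents = 15)
  set.seed(33); p2 <- samplePopulation(defaultTruth, nEvents = 15)
  expect_identical(lapply(events(p1), fluorChannel),
                   lapply(events(p2), fluorChannel))
})

test_that("a protocol that cannot stay above the drift floor errors", {
  cfg <- SimulationConfig(nTransfers = 3L,
                          dilutionOptions = c(1e6, 1e7, 1e8),
                          adaptiveDilution = FALSE)
  expect_error(simulateLineageTrajectory(cfg), "drift floor")
})

test_that("rendered capsule geometry matches closed forms", {
  ## L = W degenerates to a disc of diameter W
  img <- noiselessCell(1, 1)
  seg <- segmentEvent(img)
  expect_false(seg$empty)
  expect_equal(sum(seg$mask) * pixelArea(img), pi / 4, tolerance = 0.12)
  ## pixel-count area of a 3 x 1 um capsule near the analytic
  ## W(L-W) + pi (W/2)^2 = 2.785 um^2 (averaged over orientations)
  set.seed(9)
  areas <- replicate(20, {
    im <- renderCellImage(3, 1, runif(1, 0, pi), noiseCv = 0,
                          backgroundNoise = 0)
    sum(segmentEvent(im)$mask) * 0.09
  })
  expect_lt(abs(mean(areas) - 2.785) / 2.785, 0.05)
  ## fluorescence integrates to gfp * V * gain before noise
  img <- noiselessCell(2.5, 1, gfp = 80)
  expect_equal(sum(fluorChannel(img)), 80 * computeVolume(2.5, 1),
               tolerance = 1e-9)
  ## L < W is rejected
  expect_error(renderCellImage(1, 2), "major axis")
})

test_that("defocus strictly reduces the gradient RMS of a rendered cell", {
  sharp <- noiselessCell(3, 1)
  blurred <- renderCellImage(3, 1, orientation = 0.4, noiseCv = 0,
                             backgroundNoise = 0, phase = c(0.2, -0.3),
                             focusBlur = 2)
  expect_gt(gradientRMS(sharp), gradientRMS(blurred))
})

test_that("rasterized area error shrinks at least linearly with pixel size", {
  set.seed(4)
  errAt <- function(px) {
    mean(replicate(24, {
      im <- renderCellImage(3, 1, runif(1, 0, pi), noiseCv = 0,
                            backgroundNoise = 0, pixelArea = px^2)
      abs(sum(segmentEvent(im)$mask) * px^2 - 2.785398)
    }))
  }
  e1 <- errAt(0.3); e2 <- errAt(0.15)
  expect_lte(e2, e1 / 2)
})

test_that("sampled populations honour fractions, dispersion and means", {
  set.seed(21)
  ## all-zero contaminant fractions: every event a cell in focus
  pop <- samplePopulation(defaultTruth, nEvents = 40,
                          contaminantFractions = c(bead = 0, debris = 0,
                                                   outOfFocus = 0))
  expect_true(all(vapply(events(pop), eventLabel, "") == "cell"))
  expect_true(all(vapply(events(pop), inFocus, NA)))
  ## bead count is binomial around the declared fraction
  pop2 <- samplePopulation(defaultTruth, nEvents = 2000,
                           contaminantFractions = c(bead = 0.05, debris = 0,
                                                    outOfFocus = 0))
  nb <- sum(vapply(events(pop2), eventLabel, "") == "bead")
  expect_lt(abs(nb - 100), 3 * sqrt(2000 * 0.05 * 0.95))
  ## zero dispersion: identical cell dimensions
  pop3 <- samplePopulation(defaultTruth, nEvents = 10, cvL = 0, cvW = 0,
                           contaminantFractions = c(bead = 0, debris = 0,
                                                    outOfFocus = 0))
  Ls <- vapply(events(pop3), function(e) groundTruth(e)$L, numeric(1))
  expect_equal(length(unique(Ls)), 1L)
  ## invalid fractions error
  expect_error(samplePopulation(defaultTruth, 10,
                                contaminantFractions = c(bead = 0.6,
                                                         debris = 0.5,
                                                         outOfFocus = 0)),
               "sum")
  ## sampled means converge to the configured means (3 SE at n = 1500)
  pop4 <- samplePopulation(defaultTruth, nEvents = 1500,
                           contaminantFractions = c(bead = 0, debris = 0,
                                                    outOfFocus = 0))
  tl <- vapply(events(pop4), function(e) groundTruth(e)$L, numeric(1))
  expect_lt(abs(mean(tl) - 3), 3 * sd(tl) / sqrt(length(tl)))
})

test_that("logistic growth curves behave as the model dictates", {
  ## asymptote at the capacity
  gc <- simulateGrowthCurve(0.5, 1e5, 1e8, times = c(1, 60, 80))
  expect_equal(tail(densities(gc), 1), 1e8, tolerance = 1e-6)
  ## exponential limit: log-density linear in t with slope mu
  gc2 <- simulateGrowthCurve(0.5, 1e2, 1e12, times = seq(0, 5, 0.5))
  slopes <- diff(log(densities(gc2))) / 0.5
  expect_equal(mean(slopes), 0.5, tolerance = 1e-4)
  ## recovery of the generating rate by the estimator
  gc3 <- simulateGrowthCurve(0.5, 1e5, 1e8, times = seq(0, 20, 0.5))
  expect_equal(fitGrowthRate(gc3)$mu, 0.5, tolerance = 0.01)
  ## input validation
  expect_error(simulateGrowthCurve(0.5, 1e5, 1e8, numeric(0)), "non-empty")
  expect_error(simulateGrowthCurve(0.5, 1e9, 1e8, 1:3), "below capacity")
})
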