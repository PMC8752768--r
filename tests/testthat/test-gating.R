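test_that("gradient RMS matches hand-enumerated and degenerate cases", {
  ## constant image: zero gradient everywhere
  expect_equal(gradientRMS(matrix(5, 4, 4)), 0)
  ## single pixel: no gradient support
  expect_equal(gradientRMS(matrix(1, 1, 1)), 0)
  ## 2x2 image with unit spacing: every pixel has a one-sided difference of
  ## 1 along one axis and 0 along the other, so all four gradient
  ## magnitudes are 1 and the RMS is 1 (hand enumeration)
  expect_equal(gradientRMS(matrix(c(0, 0, 1, 1), 2, 2)), 1)
  ## blurring strictly reduces gradient energy (independent blur operator)
  set.seed(2)
  img <- fluorChannel(noiselessCell(3, 1))
  blurred <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = 2))
  expect_gt(gradientRMS(img), gradientRMS(blurred))
})

test_that("aspect ratio intensity reflects elongation of the intensity", {
  round_img <- fluorChannel(noiselessCell(1, 1))
  rod_img <- fluorChannel(noiselessCell(3, 1))
  expect_gt(aspectRatioIntensity(round_img), 0.95)
  expect_lt(aspectRatioIntensity(rod_img), 0.5)
  expect_true(is.na(aspectRatioIntensity(matrix(0, 3, 3))))
})

test_that("gating is a subset operation, idempotent, and handles empties", {
  ## empty input: empty output, zero counts
  g0 <- gateEvents(list())
  expect_equal(length(g0$sample), 0L)
  expect_true(all(g0$report$removed == 0L))
  set.seed(31)
  pop <- samplePopulation(defaultTruth, nEvents = 150)
  for (cfg in list(GateConfig(),
                   GateConfig(fluorescenceMin = 50),
                   GateConfig(aspectIntensityBounds = c(0.3, 0.9),
                              gradientRmsMin = 0.1))) {
    g1 <- gateEvents(pop, cfg)
    ids <- vapply(events(g1$sample), function(e) sum(fluorChannel(e)), 0)
    all_ids <- vapply(events(pop), function(e) sum(fluorChannel(e)), 0)
    expect_true(all(ids %in% all_ids))            # subset
    g2 <- gateEvents(g1$sample, cfg)              # idempotent
    expect_equal(length(g2$sample), length(g1$sample))
    expect_true(all(g2$report$removed == 0L))
  }
  ## all events removed: empty output with a warning, not an error
  expect_warning(gAll <- gateEvents(pop, GateConfig(fluorescenceMin = 1e9)),
                 "all events removed")
  expect_equal(length(gAll$sample), 0L)
})

test_that("raising the sharpness threshold never retains more events", {
  set.seed(17)
  pop <- samplePopulation(defaultTruth, nEvents = 120)
  kept <- vapply(c(0.05, 0.1, 0.155, 0.2, 0.3), function(thr) {
    suppressWarnings(
      length(gateEvents(pop, GateConfig(gradientRmsMin = thr))$sample))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("default gates remove labelled contaminants and keep in-focus cells", {
  set.seed(12)
  pop <- samplePopulation(defaultTruth, nEvents = 800,
                          contaminantFractions = c(bead = 0.05, debris = 0.05,
                                                   outOfFocus = 0.10))
  g <- gateEvents(pop)
  lab <- vapply(events(pop), eventLabel, "")
  foc <- vapply(events(pop), inFocus, NA)
  labG <- vapply(events(g$sample), eventLabel, "")
  focG <- vapply(events(g$sample), inFocus, NA)
  contamIn <- sum(lab != "cell" | !foc)
  contamOut <- sum(labG != "cell" | !focG)
  expect_gte((contamIn - contamOut) / contamIn, 0.99)
  cellsIn <- sum(lab == "cell" & foc)
  cellsOut <- sum(labG == "cell" & focG)
  expect_lte((cellsIn - cellsOut) / cellsIn, 0.02)
})
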