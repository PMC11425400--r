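# Synthetic-data module: scattering model, phantom and dynamic simulators.

test_that("scattering sigma is linear in depth and band-ordered", {
  m <- ScatteringModel(blurRate = c(NIR = 0.12, SWIR = 0.06))
  expect_equal(scatteringSigma(m, "NIR", 0), 0)
  expect_equal(scatteringSigma(m, "SWIR", 0), 0)
  expect_equal(scatteringSigma(m, "NIR", 10), 1.2)
  expect_equal(scatteringSigma(m, "SWIR", 10), 0.6)
  expect_equal(scatteringSigma(m, "NIR", 10) / scatteringSigma(m, "SWIR", 10),
               2)
  d <- sort(runif(5, 0, 10))
  expect_true(all(diff(scatteringSigma(m, "NIR", d)) > 0))
  expect_error(scatteringSigma(m, "NIR", -1), "depth")
})

test_that("unblurred noiseless phantom reproduces the true tube width", {
  fw <- phantomDepthExperiment("SWIR", 0, seed = 1, trueWidth = 1,
                               noise = FALSE)
  expect_equal(fw, 1, tolerance = 1e-6)
})

test_that("phantom FWHM grows with depth and is narrower in SWIR", {
  fwN <- phantomDepthExperiment("NIR", c(0, 5, 10), seed = 1, noise = FALSE)
  fwS <- phantomDepthExperiment("SWIR", c(0, 5, 10), seed = 1, noise = FALSE)
  expect_true(all(diff(fwN) > 0))
  expect_true(all(diff(fwS) > 0))
  expect_true(all(fwS[2:3] < fwN[2:3]))
  expect_error(
    simulateCapillaryPhantom(VesselSpec(rbind(c(0, 0), c(1, 1))),
                             ScatteringModel(), CameraModel("SWIR"),
                             depths = numeric(0)), "nonempty")
})

test_that("identical configuration and seed give bit-identical stacks", {
  v <- VesselSpec(rbind(c(1, 1), c(8, 1)), peakIntensity = 500)
  b <- BolusTrain(velocity = 7, startTimes = 0.3)
  cam <- CameraModel("SWIR", rows = 12, cols = 90)
  s1 <- simulateLymphStack(v, b, ScatteringModel(), cam, duration = 2,
                           seed = 11)
  s2 <- simulateLymphStack(v, b, ScatteringModel(), cam, duration = 2,
                           seed = 11)
  expect_identical(stackData(s1$stack), stackData(s2$stack))
  s3 <- simulateLymphStack(v, b, ScatteringModel(), cam, duration = 2,
                           seed = 12)
  expect_false(identical(stackData(s1$stack), stackData(s3$stack)))
})

test_that("blur preserves total intensity in noiseless background-free scenes", {
  v <- VesselSpec(rbind(c(3, 2), c(15, 2)), depth = 5, peakIntensity = 1000)
  b <- BolusTrain(velocity = 7, startTimes = 0.2)
  cam <- CameraModel("SWIR", rows = 40, cols = 180)
  noBg <- ScatteringModel(backgroundLevel = c(NIR = 0, SWIR = 0))
  noBlurNoBg <- ScatteringModel(blurRate = c(NIR = 0, SWIR = 0),
                                backgroundLevel = c(NIR = 0, SWIR = 0))
  blurred <- simulateLymphStack(v, b, noBg, cam, duration = 1, seed = 5,
                                noise = FALSE)
  flat <- simulateLymphStack(v, b, noBlurNoBg, cam, duration = 1, seed = 5,
                             noise = FALSE)
  for (f in seq_len(nFrames(blurred$stack))) {
    expect_equal(sum(stackData(blurred$stack)[, , f]),
                 sum(stackData(flat$stack)[, , f]), tolerance = 1e-6)
  }
})

test_that("a vessel-free scene is background plus noise only", {
  cam <- CameraModel("NIR", rows = 10, cols = 10)
  sim <- simulateLymphStack(list(), list(), ScatteringModel(), cam,
                            duration = 0.5, seed = 1, noise = FALSE)
  expect_true(all(stackData(sim$stack) ==
                    ScatteringModel()@backgroundLevel["NIR"]))
})

test_that("ground-truth arrival times follow distance over velocity", {
  v <- VesselSpec(rbind(c(0, 1), c(12, 1)), peakIntensity = 500)
  b <- BolusTrain(velocity = 5, startTimes = c(0.5, 2.5))
  cam <- CameraModel("SWIR", rows = 12, cols = 60)
  sim <- simulateLymphStack(v, b, ScatteringModel(), cam, duration = 1,
                            seed = 2)
  at <- arrivalTimes(sim$truth, 1, s = c(0, 10))
  expect_equal(at[, 2] - at[, 1], c(2, 2))      # 10 mm at 5 mm/s
  expect_equal(at[, 1], c(0.5, 2.5))
  ## default bolus velocity sits in the reported in vivo regime
  expect_equal(BolusTrain()@velocity, 7)
})

test_that("invalid vessel and bolus configurations are rejected", {
  expect_error(VesselSpec(rbind(c(0, 0), c(1, 1)), trueWidth = 0))
  expect_error(BolusTrain(velocity = -1))
  expect_error(BolusTrain(startTimes = c(2, 1)))
  expect_error(BolusTrain(bolusLength = 0))
  expect_error(BolusTrain(amplitude = 0))
  expect_error(
    simulateLymphStack(VesselSpec(rbind(c(0, 0), c(1, 1))), NULL,
                       ScatteringModel(), CameraModel("SWIR", rows = 4,
                                                      cols = 4),
                       duration = 0), "duration")
})

test_that("width inflation under blur is strict and grows with depth", {
  fw <- phantomDepthExperiment("SWIR", c(0, 2, 4, 8), seed = 1,
                               trueWidth = 0.22, noise = FALSE)
  expect_lt(abs(fw[1] - 0.22), 0.1)     # no blur: equality to sampling tol
  expect_true(all(fw[-1] > 0.22))
  expect_true(all(diff(fw) > 0))
})
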