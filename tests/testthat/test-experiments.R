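# End-to-end recovery experiments (reduced replicate counts; the full
# designs run in the acceptance suite).

test_that("the pipeline recovers transport velocity on single runs", {
  for (seed in 1:2) {
    ex <- velocityRecoveryExperiment(5, seed = seed)
    expect_equal(nrow(ex$events1), 3L)
    expect_equal(nrow(ex$events2), 3L)
    expect_lt(abs(ex$estimate@velocity - 5) / 5, 0.1)
    ## event times agree with ground-truth arrivals at the ROI positions
    att <- arrivalTimes(ex$truth, 1, s = 2)
    expect_true(all(abs(sort(ex$events1$time_s) - sort(att)) <= 0.3))
  }
})

test_that("cross-correlation and event matching agree on transit lag", {
  ex <- velocityRecoveryExperiment(10, seed = 3)
  expect_lt(abs(ex$estimate@velocity - 10) / 10, 0.1)
})

test_that("five simulated boluses are counted at the design SNR", {
  res <- lapply(1:3, bolusCountExperiment)
  expect_true(all(vapply(res, function(r) r$nDetected, integer(1)) == 5L))
  expect_true(all(vapply(res, function(r) r$snr, numeric(1)) >= 5))
})

test_that("band contrast on one scene favors SWIR in both statistics", {
  bc <- bandComparisonExperiment(seed = 2)
  expect_equal(bc$metrics$SWIR@nVessels, 2L)
  expect_equal(bc$metrics$NIR@nVessels, 2L)
  expect_gt(bc$ratios$distinguishabilityRatio, 1)
  expect_lt(bc$ratios$resolutionRatioMean, 1)
})
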