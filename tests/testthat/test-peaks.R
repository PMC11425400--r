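# The shared peak engine: local maxima, topographic prominence, pruning.

test_that("isolated peaks get full-height prominences", {
  x <- seq(0, 2, by = 0.1)
  y <- pmax(0, 1 - abs(x - 1) * 2)  # triangle of height 1 on zero baseline
  pk <- lymphoscope:::.detectPeaks(x, y, minProminence = 0, minSeparation = 0)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$prominence, 1)
  expect_equal(pk$position, 1)
})

test_that("two well-separated Gaussians have prominences equal to their heights", {
  x <- seq(0, 10, by = 0.05)
  y <- exp(-(x - 3)^2 / (2 * 0.3^2)) + 0.6 * exp(-(x - 7)^2 / (2 * 0.3^2))
  pk <- lymphoscope:::.detectPeaks(x, y, minProminence = 0.01,
                                   minSeparation = 0)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$prominence, c(1, 0.6), tolerance = 1e-3)
  oracle <- bruteForcePeakProminences(y)
  expect_equal(pk$prominence, oracle$prominence, tolerance = 1e-12)
})

test_that("monotone ramps contain no peaks", {
  x <- seq(0, 1, by = 0.1)
  pk <- lymphoscope:::.detectPeaks(x, x, minProminence = 0, minSeparation = 0)
  expect_equal(nrow(pk), 0L)
})

test_that("plateau maxima are reported at their leftmost sample", {
  y <- c(0, 1, 2, 2, 2, 1, 0)
  x <- as.numeric(seq_along(y))
  pk <- lymphoscope:::.detectPeaks(x, y, minProminence = 0, minSeparation = 0)
  expect_equal(pk$index, 3L)
})

test_that("prominences match the brute-force oracle on random profiles", {
  for (seed in 1:50) {
    n <- sample(20:200, 1)
    y <- randomProfile(n, seed)
    x <- as.numeric(seq_len(n))
    pk <- lymphoscope:::.detectPeaks(x, y, minProminence = 0,
                                     minSeparation = 0)
    oracle <- bruteForcePeakProminences(y)
    expect_identical(pk$index, oracle$index)
    expect_identical(pk$prominence, oracle$prominence)
  }
})

test_that("the separation filter keeps the taller of two close peaks", {
  x <- seq(0, 2, by = 0.01)
  y <- exp(-(x - 0.9)^2 / (2 * 0.05^2)) +
    0.5 * exp(-(x - 1.05)^2 / (2 * 0.05^2))
  pk <- lymphoscope:::.detectPeaks(x, y, minProminence = 0.01,
                                   minSeparation = 0.3)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position - 0.9), 0.05)
})
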