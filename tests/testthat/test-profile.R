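# Cross-section module: profile extraction, distinguishability, FWHM,
# band comparison.

test_that("background subtraction cancels a uniform frame exactly", {
  frame <- matrix(7, 20, 20)
  suppressWarnings(
    prof <- extractProfile(frame, rbind(c(2, 10), c(17, 10)),
                           backgroundFrame = frame, pixelPitch = 0.1))
  expect_true(all(intensities(prof) == 0))
  expect_true(prof@degenerate)
})

test_that("a Gaussian ridge cross-section is recovered to interpolation accuracy", {
  ## vertical ridge, transverse sigma 4 px; horizontal line across it
  img <- outer(rep(1, 40), exp(-((0:39) - 20)^2 / (2 * 4^2)))
  prof <- extractProfile(img, rbind(c(2, 20), c(38, 20)), pixelPitch = 0.1)
  expected <- exp(-(positions(prof) - 1.8)^2 / (2 * 0.4^2))
  expect_lt(max(abs(intensities(prof) - expected)), 1e-2)
})

test_that("profile positions follow polyline arclength and pixel pitch", {
  frame <- matrix(1, 10, 10)
  prof <- extractProfile(frame, rbind(c(0, 0), c(9, 9)), pixelPitch = 0.1,
                         normalize = FALSE)
  expect_equal(max(positions(prof)), 9 * sqrt(2) * 0.1, tolerance = 1e-9)
  expect_equal(positions(prof)[1], 0)
})

test_that("lines leaving the image bounds are rejected", {
  frame <- matrix(1, 10, 10)
  expect_error(extractProfile(frame, rbind(c(0, 0), c(12, 3)),
                              pixelPitch = 0.1), "bounds")
})

test_that("distinguishability follows summed prominences over vessel density", {
  mkPeaks <- function(prom) {
    new("PeakSet", peaks = data.frame(
      position = seq_along(prom), height = pmax(prom, 0.9),
      prominence = prom, fwhm = NA_real_, index = seq_along(prom) * 10L),
      params = list())
  }
  expect_equal(vesselDistinguishability(mkPeaks(1), 1), 1)
  expect_equal(vesselDistinguishability(mkPeaks(c(0.5, 0.2)), 1), 0.35)
  ## longer line, same peaks => density halves, statistic doubles
  expect_equal(vesselDistinguishability(mkPeaks(c(0.5, 0.2)), 2), 0.7)
  empty <- new("PeakSet", peaks = data.frame(
    position = numeric(0), height = numeric(0), prominence = numeric(0),
    fwhm = numeric(0), index = integer(0)), params = list())
  expect_equal(vesselDistinguishability(empty, 1), 0)
  expect_error(vesselDistinguishability(mkPeaks(1), 0), "lineLengthCm")
})

test_that("distinguishability and FWHM are invariant to intensity rescaling", {
  x <- seq(0, 6, by = 0.1)
  base <- exp(-(x - 2)^2 / (2 * 0.3^2)) + 0.7 * exp(-(x - 4.5)^2 / (2 * 0.3^2))
  img <- t(replicate(5, base))
  res <- lapply(c(1, 13.7), function(scale) {
    prof <- extractProfile(img * scale, rbind(c(0, 2), c(60, 2)),
                           pixelPitch = 0.1)
    pk <- findProfilePeaks(prof)
    list(d = vesselDistinguishability(pk, 0.6), f = resolutionFWHM(prof, pk))
  })
  expect_equal(res[[1]]$d, res[[2]]$d, tolerance = 1e-12)
  expect_equal(res[[1]]$f, res[[2]]$f, tolerance = 1e-12)
})

test_that("FWHM of an analytic Gaussian peak matches 2 sqrt(2 ln 2) sigma", {
  x <- seq(0, 8, by = 0.1)
  y <- exp(-(x - 4)^2 / (2 * 0.4^2))
  prof <- mkProfile(x, y)
  fw <- resolutionFWHM(prof, findProfilePeaks(prof))
  expect_equal(fw, 2 * sqrt(2 * log(2)) * 0.4, tolerance = 0.02)
})

test_that("FWHM of a rectangular pulse equals its width to one sample", {
  x <- seq(0, 5, by = 0.1)
  y <- as.numeric(x >= 2 & x <= 3)  # 1.0 mm boxcar
  prof <- mkProfile(x, y)
  fw <- resolutionFWHM(prof, findProfilePeaks(prof))
  expect_lt(abs(fw - 1.0), 0.1 + 1e-9)
})

test_that("overlapped-Gaussian FWHM agrees with a dense crossing search", {
  s <- 0.4
  f <- function(x) exp(-(x - 2)^2 / (2 * s^2)) +
    0.6 * exp(-(x - 2 - 2 * s)^2 / (2 * s^2))
  x <- seq(0, 6, by = 0.05)
  prof <- mkProfile(x, f(x))
  pk <- findProfilePeaks(prof, minSeparation = 0.2)
  fw <- resolutionFWHM(prof, pk)
  tab <- peakTable(pk)
  for (k in seq_len(nrow(tab))) {
    oracle <- denseCrossingFwhm(f, tab$position[k], tab$height[k] / 2,
                                lim = c(0, 6))
    expect_equal(fw[k], oracle, tolerance = 0.05)
  }
})

test_that("band ratios reproduce identity, printed-cell arithmetic and N/A rules", {
  mk <- function(d, n, res, band) new("VesselMetrics",
    distinguishability = d, nVessels = as.integer(n), lineLengthCm = 1,
    resolutionPerVessel = res, resolutionMean = mean(res),
    resolutionSd = if (length(res) > 1) sd(res) else NA_real_, band = band)
  a <- mk(0.83, 1, 0.76, "SWIR")
  b <- mk(0.81, 1, 1.26, "NIR")
  self <- compareChannels(a, a)
  expect_equal(self$distinguishabilityRatio, 1)
  expect_equal(self$resolutionRatioMean, 1)
  cmp <- compareChannels(a, b)
  expect_equal(round(cmp$distinguishabilityRatio, 2), 1.02)
  ## dissimilar peak counts: resolution ratio undefined, not an error
  cmp2 <- compareChannels(mk(0.4, 2, c(0.8, 0.9), "SWIR"), b)
  expect_false(cmp2$comparablePeaks)
  expect_true(is.na(cmp2$resolutionRatioMean))
  ## zero denominator flagged NA
  cmp3 <- compareChannels(a, mk(0, 1, 1.0, "NIR"))
  expect_true(is.na(cmp3$distinguishabilityRatio))
})

test_that("drawn-line length converts pixels to centimetres", {
  expect_equal(lineLengthCm(rbind(c(0, 0), c(100, 0)), 0.1), 1)
  expect_equal(lineLengthCm(rbind(c(0, 0), c(9, 9)), 0.1),
               9 * sqrt(2) * 0.1 / 10)
})
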