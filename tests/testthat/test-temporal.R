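# Temporal module: masking, Z-normalization, wavelet residual transform,
# bolus detection, velocity estimation.

test_that("stack-to-matrix unrolls masked pixel series faithfully", {
  st <- ImageStack(array(seq_len(2 * 2 * 3), c(2, 2, 3)))
  m1 <- PixelMask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  tsm <- stackToMatrix(st, m1)
  expect_equal(dim(tsValues(tsm)), c(1L, 3L))
  expect_equal(tsValues(tsm)[1, ], c(1, 5, 9))
  expect_equal(provenance(tsm), "raw")
  set.seed(31)
  st2 <- ImageStack(array(rnorm(4 * 4 * 5), c(4, 4, 5)))
  full <- PixelMask(matrix(TRUE, 4, 4))
  tsm2 <- stackToMatrix(st2, full)
  expect_equal(dim(tsValues(tsm2)), c(16L, 5L))
  back <- matrixToStack(tsm2, full)
  expect_identical(stackData(back), stackData(st2))
  ## random mask: every row equals its source pixel series elementwise
  set.seed(32)
  mask <- PixelMask(matrix(runif(16) < 0.5, 4, 4))
  tsm3 <- stackToMatrix(st2, mask)
  idx <- maskIndices(mask)
  for (r in seq_along(idx)) {
    rc <- arrayInd(idx[r], c(4, 4))
    expect_identical(tsValues(tsm3)[r, ], stackData(st2)[rc[1], rc[2], ])
  }
  expect_error(stackToMatrix(st2, PixelMask(matrix(TRUE, 3, 3))), "shape")
})

test_that("Z-normalization uses the population sd and guards constant rows", {
  tsm <- mkTsm(rbind(c(0, 1), c(3, 3)))
  z <- zNormalizeRows(tsm)
  expect_equal(tsValues(z)[1, ], c(-1, 1))  # population convention
  expect_equal(tsValues(z)[2, ], c(0, 0))
  expect_equal(z@degenerateRows, 2L)
  set.seed(7)
  zr <- zNormalizeRows(mkTsm(rnorm(256, mean = 40, sd = 3)))
  v <- tsValues(zr)[1, ]
  expect_lt(abs(mean(v)), 1e-12)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-12)
  expect_error(zNormalizeRows(z), "raw")
})

test_that("the periodized symlet bank reconstructs exactly", {
  for (n in c(37, 64, 150, 256)) {
    set.seed(n)
    X <- matrix(rnorm(3 * n), 3, n)
    lev <- lymphoscope:::.effectiveLevel(n, 8)
    dec <- lymphoscope:::.dwt(X, lev)
    expect_lt(max(abs(X - lymphoscope:::.idwt(dec$A, dec$D, n))), 1e-9)
  }
})

test_that("the residual transform is zero for zero input and nonnegative always", {
  z0 <- zNormalizeRows(mkTsm(rep(0, 64)))
  r0 <- waveletResidualTransform(z0)
  expect_true(all(tsValues(r0) == 0))
  set.seed(12)
  z <- zNormalizeRows(mkTsm(rbind(rnorm(100), cumsum(rnorm(100)))))
  r <- waveletResidualTransform(z)
  expect_true(all(tsValues(r) >= 0))
  expect_equal(provenance(r), "residual_squared")
  expect_error(waveletResidualTransform(zNormalizeRows(mkTsm(c(1, 2, 5)))),
               "4 samples")
})

test_that("the coarse-scale baseline absorbs a pure low-frequency trend", {
  n <- 1024
  trend <- cos(pi * (seq_len(n) - 1) / (n - 1))  # period 2n >> 2^level
  r <- waveletResidualTransform(zNormalizeRows(mkTsm(trend)))
  expect_equal(r@meta$levelUsed, 8L)
  expect_lt(max(tsValues(r)), 1e-3)
})

test_that("sharp bumps on a slow drift survive as residual maxima", {
  n <- 256
  bumpAt <- c(40, 80, 120, 160, 200)
  set.seed(1)
  row <- sin(2 * pi * seq_len(n) / n) +
    replace(rep(0, n), bumpAt, 4) + rnorm(n, sd = 0.1)
  r <- waveletResidualTransform(zNormalizeRows(mkTsm(row)))
  ev <- detectBolusPeaks(tsValues(r)[1, ], frameInterval = 1)
  expect_equal(nrow(ev), 5L)
  expect_true(all(abs(ev$frame - (bumpAt - 1)) <= 1))
})

test_that("levels are capped for short series and recorded in metadata", {
  r <- waveletResidualTransform(zNormalizeRows(mkTsm(rnorm(40))))
  expect_equal(r@meta$levelUsed, 4L)  # floor(log2(40)) - 1
  expect_equal(r@meta$levelRequested, 8L)
})

test_that("denoising lowers the error to the noiseless signal across SNR", {
  n <- 256
  sig <- sin(2 * pi * seq_len(n) / 32)
  for (snr in c(2, 5, 20)) {
    set.seed(100 + snr)
    noisy <- sig + rnorm(n, sd = sd(sig) / snr)
    lev <- lymphoscope:::.effectiveLevel(n, 8)
    dec <- lymphoscope:::.dwt(rbind(noisy), lev)
    shr <- lymphoscope:::.shrinkDetails(dec)
    den <- lymphoscope:::.idwt(dec$A, shr$D, n)[1, ]
    expect_lt(mean((den - sig)^2), mean((noisy - sig)^2))
  }
})

test_that("matrix-to-stack inverts the mask mapping", {
  m <- PixelMask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  z <- mkTsm(matrix(0, 1, 4))
  st <- matrixToStack(z, m)
  expect_true(all(stackData(st) == 0))
  expect_error(matrixToStack(mkTsm(matrix(0, 2, 4)), m), "masked pixels")
})

test_that("ROI means agree with brute-force pixel enumeration", {
  st <- ImageStack(array(1:18, c(3, 3, 2)))
  one <- PixelMask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  expect_equal(roiTimeSeries(st, one), c(1, 10))
  expect_equal(roiTimeSeries(st, PixelMask(matrix(TRUE, 3, 3))),
               c(mean(1:9), mean(10:18)))
  set.seed(4)
  big <- ImageStack(array(rnorm(20 * 20 * 6), c(20, 20, 6)))
  roi <- circleMask(20, 20, c(9, 11), 4.2)
  members <- which(maskMatrix(roi))
  flat <- matrix(stackData(big), 400, 6)
  expect_equal(roiTimeSeries(big, roi), colMeans(flat[members, ]))
})

test_that("bolus detection handles degenerate and simple series", {
  expect_equal(nrow(detectBolusPeaks(rep(1, 30), 0.1)), 0L)
  y <- c(rep(0, 10), 0.5, 1, 0.5, rep(0, 10))
  ev <- detectBolusPeaks(y, 0.1)
  expect_equal(ev$frame, 11L)              # 0-based apex frame
  expect_equal(ev$time_s, 1.1)
  expect_error(detectBolusPeaks(c(1, 2), 0.1), "3 samples")
})

test_that("velocity estimation matches events greedily and guards empty cases", {
  est <- transportVelocity(data.frame(time_s = 2),
                           data.frame(time_s = 3), path = 5)
  expect_equal(est@velocity, 5)
  expect_equal(nrow(est@pairs), 1L)
  ## simultaneous events cannot pair (dt must be strictly positive)
  est2 <- transportVelocity(data.frame(time_s = 2),
                            data.frame(time_s = 2), path = 5)
  expect_true(is.na(est2@velocity))
  expect_equal(nrow(est2@pairs), 0L)
  expect_equal(est2@unmatched1, 2)
  ## matching window closes at the next upstream event
  e1 <- data.frame(time_s = c(1, 3, 5))
  e2 <- data.frame(time_s = c(2, 4, 6))
  est3 <- transportVelocity(e1, e2, path = 7)
  expect_equal(est3@pairs$dt, c(1, 1, 1))
  expect_equal(est3@velocity, 7)
  expect_equal(est3@velocitySd, 0)
  expect_error(transportVelocity(e1, e2, path = 0), "arclength")
  expect_error(transportVelocity(e1[0, , drop = FALSE], e2, path = 1),
               "nonempty")
})

test_that("cross-correlation lag recovers a pure shift", {
  y <- exp(-((1:200) - 60)^2 / 50)
  shifted <- c(rep(0, 14), y[1:186])
  cc <- velocityByCrossCorrelation(y, shifted, frameInterval = 0.1,
                                   pathDistance = 7)
  expect_equal(cc$lag_s, 1.4)
  expect_equal(cc$velocity, 5)
})

test_that("intensity masks isolate bright pixels and respect hand-drawn bounds", {
  frame <- matrix(0, 8, 8)
  frame[4:5, 2:7] <- 100
  st <- ImageStack(array(frame, c(8, 8, 2)))
  m <- intensityMask(st)
  expect_true(all(which(maskMatrix(m)) %in%
                    which(frame > 0)))
  roi <- circleMask(8, 8, c(2, 4), 1.5)
  m2 <- intensityMask(st, within = roi)
  expect_true(all(maskMatrix(m2) <= maskMatrix(roi)))
})
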