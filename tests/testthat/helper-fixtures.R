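# Fixture builders and independent oracles shared across the test files.

mkProfile <- function(x, y, normalized = TRUE) {
  new("LineProfile", positions = x, intensities = y, rawIntensities = y,
      normalized = normalized, degenerate = FALSE)
}

mkTsm <- function(values, frameInterval = 0.1, provenance = "raw") {
  new("TimeSeriesMatrix", values = rbind(values),
      frameInterval = frameInterval, provenance = provenance,
      degenerateRows = integer(0), meta = list())
}

# Brute-force topographic prominence, straight from the definition: for
# each strict local maximum, find the nearest strictly higher sample on
# each side (or the signal edge), take the minimum over each intervening
# stretch, and subtract the higher of the two minima from the peak height.
# Independent of the package's implementation.
bruteForcePeakProminences <- function(y) {
  n <- length(y)
  idx <- which(vapply(2:(n - 1), function(i)
    y[i] > y[i - 1] && y[i] > y[i + 1], logical(1))) + 1L
  prom <- vapply(idx, function(i) {
    leftHigher <- which(y[seq_len(i - 1)] > y[i])
    lo <- if (length(leftHigher)) max(leftHigher) else 1L
    rightHigher <- which(y[(i + 1):n] > y[i])
    hi <- if (length(rightHigher)) i + min(rightHigher) else n
    y[i] - max(min(y[lo:i]), min(y[i:hi]))
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

# Dense-curve crossing oracle for FWHM: walk an analytic curve sampled at
# 1e-4 mm outward from the apex to the first crossings of the reference
# level.
denseCrossingFwhm <- function(f, apexX, ref, lim = c(-10, 10), step = 1e-4) {
  right <- seq(apexX, lim[2], by = step)
  left <- seq(apexX, lim[1], by = -step)
  xr <- right[which(f(right) <= ref)[1]]
  xl <- left[which(f(left) <= ref)[1]]
  xr - xl
}

# Smooth seeded random profile with no tied samples (almost surely).
randomProfile <- function(n, seed) {
  set.seed(seed)
  y <- cumsum(rnorm(n))
  y <- y + 2 * sin(seq(0, runif(1, 1, 4) * pi, length.out = n))
  y - min(y)
}
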