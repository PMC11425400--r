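## Temporal module: the five-step transform of per-pixel time series --
## (1) mask pixels of interest, (2) unroll to pixel x time and Z-normalize
## each row, (3) wavelet-denoise each row, (4) subtract the coarse-scale
## baseline reconstruction and square the residual, (5) refold to a stack
## -- followed by bolus peak detection and two-ROI velocity estimation.

#' Circular region-of-interest mask
#'
#' @param rows,cols frame shape in pixels.
#' @param centre (x, y) centre in 0-based pixel coordinates.
#' @param radius radius in pixels; a pixel belongs to the ROI when its
#'   centre lies within the radius.
#' @return A \code{\link{PixelMask}}.
#' @examples
#' sum(maskMatrix(circleMask(20, 20, c(10, 10), 3)))
#' @export
circleMask <- function(rows, cols, centre, radius) {
  x <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
  y <- matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
  m <- (x - centre[1])^2 + (y - centre[2])^2 <= radius^2
  if (!any(m)) stop("ROI does not cover any pixel")
  PixelMask(m)
}

#' Refine a mask by pixel intensity
#'
#' Selects pixels whose time-averaged intensity exceeds the frame median
#' by \code{k} median absolute deviations, optionally intersected with a
#' hand-drawn mask. Restricting an ROI to vessel-core pixels this way
#' keeps pure-background pixels (which contribute only noise residuals)
#' out of the temporal pipeline.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param within optional \code{\link{PixelMask}} to intersect with; it is
#'   returned unchanged if the intersection would be empty.
#' @param k MAD multiplier for the intensity threshold.
#' @return A \code{\link{PixelMask}}.
#' @examples
#' st <- ImageStack(array(c(rep(0, 12), rep(100, 4)), c(4, 4, 1)))
#' sum(maskMatrix(intensityMask(st)))
#' @export
intensityMask <- function(stack, within = NULL, k = 2) {
  avg <- apply(stack@data, c(1, 2), mean)
  sel <- avg > median(avg) + k * mad(avg)
  if (!is.null(within)) {
    sel <- sel & within@mask
    if (!any(sel)) return(within)
  }
  if (!any(sel)) stop("no pixel exceeds the intensity threshold")
  PixelMask(sel)
}

#' Unroll masked pixels to a pixel-by-time matrix
#'
#' Row r of the result is the full time series of the r-th masked pixel
#' (column-major order over the mask). The mapping is a bijection, so
#' \code{\link{matrixToStack}} inverts it exactly.
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param mask a \code{\link{PixelMask}} matching the frame shape.
#' @return A \code{\link{TimeSeriesMatrix}} with provenance \code{"raw"}.
#' @examples
#' st <- ImageStack(array(seq_len(2 * 2 * 3), c(2, 2, 3)))
#' m <- PixelMask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
#' tsValues(stackToMatrix(st, m))
#' @export
stackToMatrix <- function(stack, mask) {
  d <- dim(stack@data)
  if (!all(dim(mask@mask) == d[1:2]))
    stop("mask shape must match the stack frame shape")
  idx <- which(mask@mask)
  flat <- matrix(stack@data, d[1] * d[2], d[3])
  new("TimeSeriesMatrix", values = flat[idx, , drop = FALSE],
      frameInterval = stack@frameInterval, provenance = "raw",
      degenerateRows = integer(0), meta = list())
}

#' Z-normalize each pixel time series
#'
#' Subtracts the row mean and divides by the row standard deviation
#' (population convention, i.e. divide by n), so a two-sample row
#' \code{c(0, 1)} maps to \code{c(-1, 1)}. Constant rows cannot be
#' standardized and map to all-zero rows; their indices are recorded in
#' \code{degenerateRows}.
#'
#' @param matrix a raw \code{\link{TimeSeriesMatrix}}.
#' @return A \code{\link{TimeSeriesMatrix}} with provenance
#'   \code{"z_normalized"}.
#' @examples
#' tsm <- new("TimeSeriesMatrix", values = rbind(c(0, 1), c(3, 3)),
#'   frameInterval = 0.1, provenance = "raw", degenerateRows = integer(0),
#'   meta = list())
#' tsValues(zNormalizeRows(tsm))
#' @export
zNormalizeRows <- function(matrix) {
  if (matrix@provenance != "raw")
    stop("zNormalizeRows expects a raw TimeSeriesMatrix")
  v <- matrix@values
  mu <- rowMeans(v)
  centred <- v - mu
  sdp <- sqrt(rowMeans(centred^2))
  degen <- which(sdp == 0)
  sdp[sdp == 0] <- 1  # constant rows become all-zero
  new("TimeSeriesMatrix", values = centred / sdp,
      frameInterval = matrix@frameInterval, provenance = "z_normalized",
      degenerateRows = as.integer(degen), meta = matrix@meta)
}

#' Wavelet residual transform of pixel time series
#'
#' Per row: (a) denoise by a level-capped symlet discrete wavelet
#' transform with empirical-Bayes posterior-median shrinkage of the detail
#' coefficients, using one noise estimate per row (median absolute
#' finest-level detail / 0.6745) shared across levels; (b) reconstruct a
#' smooth baseline from only the final-level approximation (scaling)
#' coefficients, all detail bands zeroed; (c) return the squared
#' difference between the denoised row and that baseline. Squaring removes
#' negative excursions, so transiting boluses stand out as nonnegative
#' transient peaks over a flat background. The level actually used
#' (\code{min(level, floor(log2(n)) - 1)}) is recorded in \code{meta}.
#'
#' @param matrix a Z-normalized \code{\link{TimeSeriesMatrix}} with at
#'   least 4 time points.
#' @param params a \code{\link{WaveletParams}}.
#' @return A \code{\link{TimeSeriesMatrix}} with provenance
#'   \code{"residual_squared"}; all values >= 0.
#' @examples
#' set.seed(1)
#' raw <- new("TimeSeriesMatrix",
#'   values = rbind(sin(seq(0, pi, length.out = 128)) +
#'                    c(rep(0, 60), 3, rep(0, 67)) + rnorm(128, sd = .05)),
#'   frameInterval = 0.1, provenance = "raw", degenerateRows = integer(0),
#'   meta = list())
#' res <- waveletResidualTransform(zNormalizeRows(raw))
#' which.max(tsValues(res)[1, ])  # near frame 61
#' @export
waveletResidualTransform <- function(matrix, params = WaveletParams()) {
  if (matrix@provenance != "z_normalized")
    stop("waveletResidualTransform expects a z_normalized TimeSeriesMatrix")
  n <- ncol(matrix@values)
  if (n < 4L) stop("time series must have at least 4 samples")
  lev <- .effectiveLevel(n, params@level)
  dec <- .dwt(matrix@values, lev, params@family)
  shr <- .shrinkDetails(dec)
  ## denoised - baseline = inverse transform of the shrunken details with
  ## the approximation zeroed (linearity of the synthesis bank)
  resid <- .idwt(dec$A * 0, shr$D, n, params@family)
  new("TimeSeriesMatrix", values = resid^2,
      frameInterval = matrix@frameInterval, provenance = "residual_squared",
      degenerateRows = matrix@degenerateRows,
      meta = c(matrix@meta,
               list(waveletFamily = params@family, levelRequested =
                      params@level, levelUsed = lev, noiseSigma = shr$sigma)))
}

#' Refold a pixel-by-time matrix into an image stack
#'
#' Inverse of \code{\link{stackToMatrix}} on the mask: masked pixels are
#' filled from the matrix rows, unmasked pixels are zero.
#'
#' @param matrix a \code{\link{TimeSeriesMatrix}}.
#' @param mask the \code{\link{PixelMask}} used to unroll.
#' @param pixelPitch mm/pixel of the rebuilt stack.
#' @param band spectral band label for the rebuilt stack.
#' @return An \code{\link{ImageStack}}.
#' @examples
#' st <- ImageStack(array(rnorm(32), c(4, 4, 2)))
#' m <- PixelMask(matrix(rep(c(TRUE, FALSE), 8), 4, 4))
#' back <- matrixToStack(stackToMatrix(st, m), m)
#' all(stackData(back)[maskMatrix(m)] == stackData(st)[maskMatrix(m)])
#' @export
matrixToStack <- function(matrix, mask, pixelPitch = 0.1, band = "SWIR") {
  idx <- which(mask@mask)
  if (nrow(matrix@values) != length(idx))
    stop("matrix rows must equal the number of masked pixels")
  d <- dim(mask@mask)
  nf <- ncol(matrix@values)
  flat <- base::matrix(0, d[1] * d[2], nf)
  flat[idx, ] <- matrix@values
  ImageStack(array(flat, c(d, nf)), pixelPitch = pixelPitch,
             frameInterval = matrix@frameInterval, band = band)
}

#' Mean time series over a region of interest
#'
#' @param stack an \code{\link{ImageStack}}.
#' @param roi a \code{\link{PixelMask}} matching the frame shape.
#' @return Numeric vector: per-frame mean over the ROI pixels.
#' @examples
#' st <- ImageStack(array(1:18, c(3, 3, 2)))
#' roiTimeSeries(st, PixelMask(matrix(TRUE, 3, 3)))
#' @export
roiTimeSeries <- function(stack, roi) {
  d <- dim(stack@data)
  if (!all(dim(roi@mask) == d[1:2]))
    stop("ROI shape must match the stack frame shape")
  idx <- which(roi@mask)
  if (!length(idx)) stop("ROI does not cover any pixel")
  flat <- matrix(stack@data, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Detect lymph bolus transits in an ROI time series
#'
#' Applies the same topographic-prominence peak rule as the cross-section
#' detector to the time axis. Event times are \code{frame * frameInterval}
#' with 0-based frames (frame 0 is t = 0). Peaks close to the series ends
#' are flagged \code{boundary}, because the symmetric signal extension
#' used by the wavelet transform makes edge responses less reliable.
#'
#' @param series numeric time series (length >= 3), typically the ROI mean
#'   of a residual-squared stack.
#' @param frameInterval seconds per frame.
#' @param minProminence smallest retained prominence, in series units.
#'   The default, a quarter of the series range, is calibrated for
#'   residual-squared series, whose background is near zero: it rejects
#'   residual noise spikes while keeping transit peaks attenuated by blur
#'   or partial passage.
#' @param minSeparationS smallest allowed spacing between events, s.
#' @param roiId label attached to the events.
#' @param boundaryFrames how many frames from either end are flagged.
#' @return data.frame: \code{roi_id}, \code{frame} (0-based),
#'   \code{time_s}, \code{value}, \code{prominence}, \code{boundary}.
#' @examples
#' y <- rep(0, 50); y[c(11, 31)] <- c(1, 0.8)
#' detectBolusPeaks(y, frameInterval = 0.1)
#' @export
detectBolusPeaks <- function(series, frameInterval, minProminence = NULL,
                             minSeparationS = 0.5, roiId = "roi",
                             boundaryFrames = 8L) {
  if (length(series) < 3L) stop("series must have at least 3 samples")
  if (is.null(minProminence))
    minProminence <- 0.25 * diff(range(series))
  t <- (seq_along(series) - 1L) * frameInterval
  pk <- .detectPeaks(t, series, minProminence = minProminence,
                     minSeparation = minSeparationS)
  data.frame(roi_id = rep(roiId, nrow(pk)), frame = pk$index - 1L,
             time_s = pk$position, value = pk$height,
             prominence = pk$prominence,
             boundary = pk$index <= boundaryFrames |
               pk$index > length(series) - boundaryFrames)
}

#' Bolus transport velocity from two ROIs on one vessel
#'
#' Matches bolus events between an upstream and a downstream ROI by
#' greedy forward matching: each upstream event is paired with the
#' earliest unused downstream event occurring strictly after it and
#' before the next upstream event. Each pair yields velocity = path
#' arclength / transit time; the estimate is the mean +/- sd over pairs.
#' Pairs with non-positive transit time cannot arise by construction;
#' when no pair can be formed the estimate is returned empty (velocity
#' \code{NA}) rather than raising an error.
#'
#' @param events1,events2 event data.frames from
#'   \code{\link{detectBolusPeaks}} (upstream, downstream); only
#'   \code{time_s} is used.
#' @param path the vessel path between the two ROIs: either its arclength
#'   in mm, or an n x 2 matrix of (x, y) vertices in mm.
#' @return A \code{\link{VelocityEstimate}}.
#' @examples
#' e1 <- data.frame(time_s = 2); e2 <- data.frame(time_s = 3)
#' transportVelocity(e1, e2, path = 5)  # 5 mm / 1 s
#' @export
transportVelocity <- function(events1, events2, path) {
  dist <- if (is.matrix(path)) .polylineLength(path) else as.numeric(path)
  if (dist <= 0) stop("path arclength must be > 0")
  if (!nrow(events1) || !nrow(events2))
    stop("both event lists must be nonempty")
  t1 <- sort(events1$time_s)
  t2 <- sort(events2$time_s)
  used <- logical(length(t2))
  pairs <- list()
  for (i in seq_along(t1)) {
    upper <- if (i < length(t1)) t1[i + 1L] else Inf
    j <- which(!used & t2 > t1[i] & t2 < upper)
    if (!length(j)) next
    j <- j[1L]
    used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(t1 = t1[i], t2 = t2[j])
  }
  if (length(pairs)) {
    tab <- do.call(rbind, pairs)
    pairsDf <- data.frame(t1 = tab[, "t1"], t2 = tab[, "t2"],
                          dt = tab[, "t2"] - tab[, "t1"])
    pairsDf$velocity <- dist / pairsDf$dt
    vel <- mean(pairsDf$velocity)
    velSd <- if (nrow(pairsDf) > 1) sd(pairsDf$velocity) else NA_real_
  } else {
    pairsDf <- data.frame(t1 = numeric(0), t2 = numeric(0),
                          dt = numeric(0), velocity = numeric(0))
    vel <- NA_real_
    velSd <- NA_real_
  }
  matched1 <- if (nrow(pairsDf)) pairsDf$t1 else numeric(0)
  matched2 <- if (nrow(pairsDf)) pairsDf$t2 else numeric(0)
  new("VelocityEstimate", velocity = vel, velocitySd = velSd,
      pathDistance = dist, pairs = pairsDf,
      unmatched1 = setdiff(t1, matched1), unmatched2 = setdiff(t2, matched2))
}

#' Transit lag by cross-correlation (cross-check estimator)
#'
#' Alternative to event matching: the lag maximizing the cross-correlation
#' of the two ROI series gives the transit time directly. Used as an
#' independent check on \code{\link{transportVelocity}} when the event
#' pairing is ambiguous.
#'
#' @param series1,series2 upstream and downstream ROI time series.
#' @param frameInterval seconds per frame.
#' @param pathDistance arclength between the ROIs, mm.
#' @return A list: \code{lag_s} (positive when series2 trails series1) and
#'   \code{velocity} (mm/s; \code{NA} when the best lag is not positive).
#' @examples
#' y <- exp(-((1:100) - 30)^2 / 20)
#' velocityByCrossCorrelation(y, c(rep(0, 10), y[1:90]), 0.1, 7)
#' @export
velocityByCrossCorrelation <- function(series1, series2, frameInterval,
                                       pathDistance) {
  n <- length(series1)
  stopifnot(length(series2) == n)
  a <- series1 - mean(series1)
  b <- series2 - mean(series2)
  lags <- seq(-(n - 1L), n - 1L)
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(a[seq_len(n - L)] * b[seq_len(n - L) + L])
    else sum(b[seq_len(n + L)] * a[seq_len(n + L) - L])
  }, numeric(1))
  best <- lags[which.max(cc)]
  lagS <- best * frameInterval
  list(lag_s = lagS,
       velocity = if (lagS > 0) pathDistance / lagS else NA_real_)
}
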