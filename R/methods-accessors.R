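#' @describeIn lymphoscope-accessors the (row, col, frame) array of an
#'   \code{ImageStack}.
#' @export
setMethod("stackData", "ImageStack", function(object, ...) object@data)

#' @describeIn lymphoscope-accessors mm/pixel of an \code{ImageStack}.
#' @export
setMethod("pixelPitch", "ImageStack", function(object, ...) object@pixelPitch)

#' @describeIn lymphoscope-accessors s/frame of an \code{ImageStack}.
#' @export
setMethod("frameInterval", "ImageStack",
          function(object, ...) object@frameInterval)

#' @describeIn lymphoscope-accessors s/frame of a \code{TimeSeriesMatrix}.
#' @export
setMethod("frameInterval", "TimeSeriesMatrix",
          function(object, ...) object@frameInterval)

#' @describeIn lymphoscope-accessors spectral band of an \code{ImageStack}.
#' @export
setMethod("band", "ImageStack", function(object, ...) object@band)

#' @describeIn lymphoscope-accessors spectral band of a \code{CameraModel}.
#' @export
setMethod("band", "CameraModel", function(object, ...) object@band)

#' @describeIn lymphoscope-accessors number of frames in an
#'   \code{ImageStack}.
#' @export
setMethod("nFrames", "ImageStack", function(object, ...) dim(object@data)[3])

#' @describeIn lymphoscope-accessors the pixel x time matrix of a
#'   \code{TimeSeriesMatrix}.
#' @export
setMethod("tsValues", "TimeSeriesMatrix", function(object, ...) object@values)

#' @describeIn lymphoscope-accessors processing stage of a
#'   \code{TimeSeriesMatrix}.
#' @export
setMethod("provenance", "TimeSeriesMatrix",
          function(object, ...) object@provenance)

#' @describeIn lymphoscope-accessors logical matrix of a \code{PixelMask}.
#' @export
setMethod("maskMatrix", "PixelMask", function(object, ...) object@mask)

#' @describeIn lymphoscope-accessors column-major linear indices of the
#'   masked pixels (the matrix-row order).
#' @export
setMethod("maskIndices", "PixelMask", function(object, ...)
  which(object@mask))

#' @describeIn lymphoscope-accessors peak data.frame of a \code{PeakSet}.
#' @export
setMethod("peakTable", "PeakSet", function(object, ...) object@peaks)

#' @describeIn lymphoscope-accessors positions (mm) of a
#'   \code{LineProfile}.
#' @export
setMethod("positions", "LineProfile", function(object, ...) object@positions)

#' @describeIn lymphoscope-accessors processed intensities of a
#'   \code{LineProfile}.
#' @export
setMethod("intensities", "LineProfile",
          function(object, ...) object@intensities)

#' @export
#' @describeIn arrivalTimes arrival-time matrix for one vessel of a
#'   simulated scene.
setMethod("arrivalTimes", "GroundTruth", function(object, vessel = 1L, s = 0) {
  trains <- object@boluses[[vessel]]
  starts <- unlist(lapply(trains, function(tr)
    tr@startTimes), use.names = FALSE)
  vels <- unlist(lapply(trains, function(tr)
    rep(tr@velocity, length(tr@startTimes))), use.names = FALSE)
  ord <- order(starts)
  out <- outer(seq_along(starts), seq_along(s),
               function(i, j) starts[ord][i] + s[j] / vels[ord][i])
  if (length(s) == 1L) drop(out) else out
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ImageStack: %d x %d pixels, %d frame(s), band %s\n", d[1], d[2], d[3],
    object@band))
  cat(sprintf("  pixel pitch %.4g mm/px, frame interval %.4g s, %d-bit\n",
              object@pixelPitch, object@frameInterval, object@bitDepth))
})

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat(sprintf("TimeSeriesMatrix: %d pixel(s) x %d frame(s) [%s]\n",
              nrow(object@values), ncol(object@values), object@provenance))
  if (length(object@degenerateRows))
    cat(sprintf("  %d degenerate (constant) row(s)\n",
                length(object@degenerateRows)))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peak(s)\n", nrow(object@peaks)))
  if (nrow(object@peaks)) print(object@peaks, digits = 4)
})

setMethod("show", "VesselMetrics", function(object) {
  cat(sprintf(
    "VesselMetrics [%s]: distinguishability %.3f (%d vessel(s) on %.3f cm)\n",
    object@band, object@distinguishability, object@nVessels,
    object@lineLengthCm))
  if (length(object@resolutionPerVessel))
    cat(sprintf("  resolution %.3f +/- %.3f mm\n", object@resolutionMean,
                object@resolutionSd))
})

setMethod("show", "VelocityEstimate", function(object) {
  cat(sprintf(
    "VelocityEstimate: %.3f +/- %.3f mm/s over %d pair(s), path %.2f mm\n",
    object@velocity, object@velocitySd, nrow(object@pairs),
    object@pathDistance))
})
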