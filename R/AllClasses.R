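## Central S4 containers. Calibration is carried with the data so that all
## downstream statistics are reported in physical units (mm, s, counts).

.BANDS <- c("NIR", "SWIR")

#' Camera sensor model
#'
#' Geometry and noise parameters of one imaging camera. Defaults follow the
#' two sensors of a dual-band lymphangiography rig: a 512x512 16-bit
#' intensified CCD for the NIR-I channel and a 512x640 16-bit InGaAs focal
#' plane array for the SWIR channel.
#'
#' @slot rows,cols sensor size in pixels.
#' @slot bitDepth bits per sample; intensities are clipped to
#'   \code{[0, 2^bitDepth - 1]}.
#' @slot readNoiseSd Gaussian read noise standard deviation, counts.
#' @slot gain counts per detected photon.
#' @slot band \code{"NIR"} or \code{"SWIR"}.
#' @exportClass CameraModel
setClass("CameraModel",
  representation(rows = "integer", cols = "integer", bitDepth = "integer",
                 readNoiseSd = "numeric", gain = "numeric", band = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@rows < 1L || object@cols < 1L)
      msg <- c(msg, "rows and cols must be positive")
    if (object@bitDepth < 1L) msg <- c(msg, "bitDepth must be positive")
    if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
    if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
    if (!object@band %in% .BANDS)
      msg <- c(msg, "band must be 'NIR' or 'SWIR'")
    if (is.null(msg)) TRUE else msg
  })

#' @param band \code{"NIR"} or \code{"SWIR"}; picks the default geometry.
#' @param rows,cols sensor size in pixels.
#' @param bitDepth bits per sample.
#' @param readNoiseSd Gaussian read noise sd, counts.
#' @param gain counts per photon.
#' @return A \code{CameraModel} object.
#' @examples
#' CameraModel("SWIR")
#' @rdname CameraModel-class
#' @export
CameraModel <- function(band = c("NIR", "SWIR"), rows = NULL, cols = NULL,
                        bitDepth = 16L, readNoiseSd = 10, gain = 1) {
  band <- match.arg(band)
  if (is.null(rows)) rows <- 512L
  if (is.null(cols)) cols <- if (band == "SWIR") 640L else 512L
  new("CameraModel", rows = as.integer(rows), cols = as.integer(cols),
      bitDepth = as.integer(bitDepth), readNoiseSd = as.numeric(readNoiseSd),
      gain = as.numeric(gain), band = band)
}

#' Tissue scattering and background model
#'
#' Depth-dependent Gaussian point-spread blur and additive autofluorescence
#' background, per spectral band. The PSF sigma grows linearly with imaging
#' depth at \code{blurRate} mm of sigma per mm of depth. Photon scattering
#' and tissue autofluorescence are both weaker in the SWIR window, so the
#' defaults satisfy \code{blurRate["NIR"] > blurRate["SWIR"]} and
#' \code{backgroundLevel["NIR"] > backgroundLevel["SWIR"]}.
#'
#' @slot blurRate named numeric (NIR, SWIR): PSF sigma per unit depth,
#'   mm/mm.
#' @slot backgroundLevel named numeric (NIR, SWIR): uniform background,
#'   counts.
#' @exportClass ScatteringModel
setClass("ScatteringModel",
  representation(blurRate = "numeric", backgroundLevel = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(.BANDS %in% names(object@blurRate)))
      msg <- c(msg, "blurRate must be named with 'NIR' and 'SWIR'")
    if (!all(.BANDS %in% names(object@backgroundLevel)))
      msg <- c(msg, "backgroundLevel must be named with 'NIR' and 'SWIR'")
    if (any(object@blurRate < 0)) msg <- c(msg, "blurRate must be >= 0")
    if (any(object@backgroundLevel < 0))
      msg <- c(msg, "backgroundLevel must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param blurRate named numeric, PSF sigma growth per mm depth per band.
#' @param backgroundLevel named numeric, background counts per band.
#' @return A \code{ScatteringModel} object.
#' @examples
#' ScatteringModel()
#' @rdname ScatteringModel-class
#' @export
ScatteringModel <- function(blurRate = c(NIR = 0.12, SWIR = 0.06),
                            backgroundLevel = c(NIR = 300, SWIR = 60)) {
  new("ScatteringModel", blurRate = blurRate, backgroundLevel = backgroundLevel)
}

#' Vessel geometry specification
#'
#' A lymphatic vessel as a polyline centerline in physical coordinates with
#' a transverse width, an imaging depth and a peak fluorescence intensity.
#' The default \code{trueWidth} of 0.22 mm is the anatomical lymphatic
#' vessel diameter measured post-mortem with Evan's blue dye; fluorescence
#' cross-sections appear wider than this because of scattering blur.
#'
#' @slot centerline n x 2 matrix of (x, y) positions, mm.
#' @slot trueWidth transverse vessel width, mm.
#' @slot depth imaging depth below the surface, mm.
#' @slot peakIntensity fluorescence signal of the filled vessel, counts.
#' @exportClass VesselSpec
setClass("VesselSpec",
  representation(centerline = "matrix", trueWidth = "numeric",
                 depth = "numeric", peakIntensity = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@centerline) < 2L || ncol(object@centerline) != 2L)
      msg <- c(msg, "centerline must be an n x 2 matrix with n >= 2")
    if (object@trueWidth <= 0) msg <- c(msg, "trueWidth must be > 0")
    if (object@depth < 0) msg <- c(msg, "depth must be >= 0")
    if (object@peakIntensity <= 0) msg <- c(msg, "peakIntensity must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param centerline n x 2 matrix of (x, y) vertices in mm.
#' @param trueWidth vessel width, mm.
#' @param depth imaging depth, mm.
#' @param peakIntensity vessel signal, counts.
#' @return A \code{VesselSpec} object.
#' @examples
#' VesselSpec(rbind(c(1, 1), c(15, 1)))
#' @rdname VesselSpec-class
#' @export
VesselSpec <- function(centerline, trueWidth = 0.22, depth = 1,
                       peakIntensity = 2000) {
  new("VesselSpec", centerline = rbind(centerline), trueWidth = trueWidth,
      depth = depth, peakIntensity = peakIntensity)
}

#' Lymph bolus train
#'
#' Periodic packets of lymph advected along a vessel centerline. Each bolus
#' is a 1-D Gaussian intensity packet in arclength whose full width at half
#' maximum is \code{bolusLength}; the packet centre enters the vessel at
#' arclength 0 at each start time and travels at \code{velocity}. The
#' default velocity of 7 mm/s sits in the regime observed in vivo for
#' rat lymphatics (about 6.4-7.1 mm/s).
#'
#' @slot velocity transport velocity, mm/s.
#' @slot startTimes times at which successive boluses enter the vessel, s.
#' @slot bolusLength FWHM of the packet along the vessel, mm.
#' @slot amplitude packet amplitude as a fraction of the vessel's
#'   \code{peakIntensity}.
#' @exportClass BolusTrain
setClass("BolusTrain",
  representation(velocity = "numeric", startTimes = "numeric",
                 bolusLength = "numeric", amplitude = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@velocity <= 0) msg <- c(msg, "velocity must be > 0")
    if (length(object@startTimes) < 1L ||
        is.unsorted(object@startTimes, strictly = TRUE))
      msg <- c(msg, "startTimes must be nonempty and strictly increasing")
    if (object@bolusLength <= 0) msg <- c(msg, "bolusLength must be > 0")
    if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param velocity transport velocity, mm/s.
#' @param startTimes strictly increasing entry times, s.
#' @param bolusLength packet FWHM along the vessel, mm.
#' @param amplitude fraction of the vessel peak intensity.
#' @return A \code{BolusTrain} object.
#' @examples
#' BolusTrain(velocity = 7, startTimes = c(1, 3, 5))
#' @rdname BolusTrain-class
#' @export
BolusTrain <- function(velocity = 7, startTimes = c(1, 3, 5),
                       bolusLength = 2, amplitude = 1) {
  new("BolusTrain", velocity = velocity, startTimes = as.numeric(startTimes),
      bolusLength = bolusLength, amplitude = amplitude)
}

#' Calibrated dynamic image stack
#'
#' A (row, col, frame) intensity array with its physical calibration: the
#' pixel pitch in mm/pixel and the frame interval in seconds. Pixel indices
#' are 0-based in physical conversions; the physical position of a pixel is
#' its centre index times the pixel pitch.
#'
#' @slot data numeric array, dimensions (row, col, frame); counts.
#' @slot pixelPitch mm per pixel.
#' @slot frameInterval seconds per frame.
#' @slot band \code{"NIR"} or \code{"SWIR"}.
#' @slot bitDepth camera bit depth the counts refer to.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", pixelPitch = "numeric",
                 frameInterval = "numeric", band = "character",
                 bitDepth = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D (row, col, frame) array")
    if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (!object@band %in% .BANDS)
      msg <- c(msg, "band must be 'NIR' or 'SWIR'")
    if (is.null(msg)) TRUE else msg
  })

#' @param data 3-D array (row, col, frame) or a matrix (treated as one
#'   frame).
#' @param pixelPitch mm/pixel.
#' @param frameInterval s/frame.
#' @param band spectral band label.
#' @param bitDepth camera bit depth.
#' @return An \code{ImageStack} object.
#' @examples
#' ImageStack(array(0, c(8, 8, 3)), pixelPitch = 0.1, frameInterval = 0.1)
#' @rdname ImageStack-class
#' @export
ImageStack <- function(data, pixelPitch = 0.1, frameInterval = 0.1,
                       band = "SWIR", bitDepth = 16L) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("ImageStack", data = data, pixelPitch = pixelPitch,
      frameInterval = frameInterval, band = band,
      bitDepth = as.integer(bitDepth))
}

#' Simulation ground truth
#'
#' Complete record of a simulated scene: vessel geometries, bolus trains
#' (one list element per vessel, each a list of \code{BolusTrain}) and the
#' seed. Together with the scene configuration the seed fully determines
#' the generated stack. True bolus arrival times at any arclength are
#' recovered with \code{\link{arrivalTimes}}.
#'
#' @slot vessels list of \code{VesselSpec}.
#' @slot boluses list (per vessel) of lists of \code{BolusTrain}.
#' @slot seed integer seed used for the stochastic parts.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(vessels = "list", boluses = "list", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@boluses) != length(object@vessels))
      msg <- c(msg, "boluses must have one element per vessel")
    if (is.null(msg)) TRUE else msg
  })

#' Intensity profile along a drawn line
#'
#' Intensities sampled by bilinear interpolation along a polyline drawn
#' across vessels, with positions in mm from the start of the line. When
#' background subtraction is requested the background frame is sampled at
#' identical positions and subtracted before flooring at zero; when
#' normalization is requested the profile is divided by its maximum.
#'
#' @slot positions mm along the line, starting at 0.
#' @slot intensities processed (background-subtracted, possibly normalized)
#'   intensities.
#' @slot rawIntensities intensities as sampled, counts.
#' @slot normalized logical, whether max-normalization was applied.
#' @slot degenerate logical, \code{TRUE} when normalization was requested
#'   on an all-zero profile.
#' @exportClass LineProfile
setClass("LineProfile",
  representation(positions = "numeric", intensities = "numeric",
                 rawIntensities = "numeric", normalized = "logical",
                 degenerate = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@positions)
    if (length(object@intensities) != n || length(object@rawIntensities) != n)
      msg <- c(msg, "positions and intensity arrays must have equal length")
    if (n > 0 && (object@positions[1] != 0 ||
                  is.unsorted(object@positions, strictly = TRUE)))
      msg <- c(msg, "positions must start at 0 and increase strictly")
    if (is.null(msg)) TRUE else msg
  })

#' Detected peaks on a profile or time series
#'
#' One row per retained peak: position (mm, or s for time series), height,
#' topographic prominence, and full width at half maximum (NA when the
#' half-maximum crossings are not bracketed before a higher saddle or the
#' profile edge). The detection parameters are kept as metadata.
#'
#' @slot peaks data.frame with columns \code{position}, \code{height},
#'   \code{prominence}, \code{fwhm}, \code{index}.
#' @slot params list of detection parameters (min prominence, min
#'   separation, FWHM reference rule).
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "data.frame", params = "list"),
  validity = function(object) {
    need <- c("position", "height", "prominence", "fwhm", "index")
    msg <- NULL
    if (!all(need %in% names(object@peaks)))
      msg <- c(msg, paste("peaks must have columns:",
                          paste(need, collapse = ", ")))
    else {
      ok <- nrow(object@peaks) == 0 ||
        all(object@peaks$prominence > 0 &
              object@peaks$prominence <= object@peaks$height + 1e-12)
      if (!ok) msg <- c(msg, "prominences must be in (0, height]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Architectural metrics for one drawn line
#'
#' Vessel distinguishability (summed peak prominences divided by vessels
#' per cm of drawn line) and FWHM resolution summaries for the peaks found
#' on one cross-section line in one spectral band.
#'
#' @slot distinguishability dimensionless; 0 when no peaks.
#' @slot nVessels detected peak count.
#' @slot lineLengthCm drawn-line arclength, cm.
#' @slot resolutionPerVessel per-peak FWHM, mm (NA where unmeasurable).
#' @slot resolutionMean,resolutionSd summary of the per-peak FWHM, mm.
#' @slot band spectral band label.
#' @exportClass VesselMetrics
setClass("VesselMetrics",
  representation(distinguishability = "numeric", nVessels = "integer",
                 lineLengthCm = "numeric", resolutionPerVessel = "numeric",
                 resolutionMean = "numeric", resolutionSd = "numeric",
                 band = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@distinguishability < 0)
      msg <- c(msg, "distinguishability must be >= 0")
    if (object@lineLengthCm <= 0) msg <- c(msg, "lineLengthCm must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Mask of pixels of interest
#'
#' A logical image selecting the pixels whose time series enter the
#' temporal pipeline. Masked pixels map to matrix rows in column-major
#' order; the mapping is a bijection, so stack -> matrix -> stack is the
#' identity on the mask.
#'
#' @slot mask logical matrix (row, col).
#' @exportClass PixelMask
setClass("PixelMask",
  representation(mask = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (sum(object@mask) < 1L) msg <- c(msg, "mask must select >= 1 pixel")
    if (is.null(msg)) TRUE else msg
  })

#' @param mask logical matrix.
#' @return A \code{PixelMask} object.
#' @rdname PixelMask-class
#' @export
PixelMask <- function(mask) new("PixelMask", mask = mask)

#' Pixel-by-time matrix
#'
#' Masked pixel time series unrolled to a (pixel x time) array. The
#' \code{provenance} slot records the processing stage: \code{raw},
#' \code{z_normalized}, \code{denoised} or \code{residual_squared}.
#' \code{degenerateRows} lists rows whose raw series was constant (their
#' Z-normalized form is all-zero by convention).
#'
#' @slot values numeric matrix, pixels x frames.
#' @slot frameInterval seconds per frame.
#' @slot provenance processing stage.
#' @slot degenerateRows integer indices of constant rows.
#' @slot meta list of processing metadata (e.g. wavelet level actually
#'   used).
#' @exportClass TimeSeriesMatrix
setClass("TimeSeriesMatrix",
  representation(values = "matrix", frameInterval = "numeric",
                 provenance = "character", degenerateRows = "integer",
                 meta = "list"),
  validity = function(object) {
    stages <- c("raw", "z_normalized", "denoised", "residual_squared")
    msg <- NULL
    if (!object@provenance %in% stages)
      msg <- c(msg, paste("provenance must be one of:",
                          paste(stages, collapse = ", ")))
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Wavelet denoising parameters
#'
#' Configuration of the per-row wavelet denoising step: symlet family
#' (order 8 by default), decomposition level (8 by default, capped at
#' \code{floor(log2(n)) - 1} for short series), empirical-Bayes
#' posterior-median shrinkage, and a single level-independent noise
#' estimate from the median absolute deviation of the finest-level detail
#' coefficients divided by 0.6745.
#'
#' @slot family wavelet family name (currently \code{"sym8"}).
#' @slot level requested decomposition depth.
#' @slot method denoising rule (\code{"ebayes"}).
#' @slot thresholding shrinkage rule (\code{"median"} = posterior median).
#' @slot noiseEstimate noise rule (\code{"level_independent"}).
#' @exportClass WaveletParams
setClass("WaveletParams",
  representation(family = "character", level = "integer", method = "character",
                 thresholding = "character", noiseEstimate = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@family %in% names(.WAVELET_FILTERS))
      msg <- c(msg, paste("unsupported wavelet family:", object@family))
    if (object@level < 1L) msg <- c(msg, "level must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @param family wavelet family (\code{"sym8"}).
#' @param level decomposition depth.
#' @param method denoising method (\code{"ebayes"}).
#' @param thresholding shrinkage rule (\code{"median"}).
#' @param noiseEstimate noise estimation rule (\code{"level_independent"}).
#' @return A \code{WaveletParams} object.
#' @examples
#' WaveletParams()
#' @rdname WaveletParams-class
#' @export
WaveletParams <- function(family = "sym8", level = 8L, method = "ebayes",
                          thresholding = "median",
                          noiseEstimate = "level_independent") {
  new("WaveletParams", family = family, level = as.integer(level),
      method = method, thresholding = thresholding,
      noiseEstimate = noiseEstimate)
}

#' Transport velocity estimate
#'
#' Result of matching bolus events between two regions of interest on the
#' same vessel. Each ROI-1 event is matched to the earliest ROI-2 event
#' that occurs strictly after it and before the next ROI-1 event; each
#' matched pair yields velocity = path arclength / transit time, and the
#' estimate is the mean +/- sd over pairs.
#'
#' @slot velocity mean velocity over matched pairs, mm/s (NA when empty).
#' @slot velocitySd sd over matched pairs, mm/s.
#' @slot pathDistance arclength between the ROIs, mm.
#' @slot pairs data.frame: \code{t1}, \code{t2}, \code{dt}, \code{velocity}.
#' @slot unmatched1,unmatched2 times of unmatched events in each ROI, s.
#' @exportClass VelocityEstimate
setClass("VelocityEstimate",
  representation(velocity = "numeric", velocitySd = "numeric",
                 pathDistance = "numeric", pairs = "data.frame",
                 unmatched1 = "numeric", unmatched2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@pathDistance <= 0) msg <- c(msg, "pathDistance must be > 0")
    if (nrow(object@pairs) > 0 && any(object@pairs$dt <= 0))
      msg <- c(msg, "matched pairs must have positive transit times")
    if (is.null(msg)) TRUE else msg
  })

#' Dual-band composite image
#'
#' RGB rendering of co-registered NIR and SWIR frames: after independent
#' max-normalization the NIR channel drives red and blue (purple) and the
#' SWIR channel drives green, so pixels bright in both bands render white.
#'
#' @slot rgb numeric array (row, col, 3) in [0, 1].
#' @slot provenance list mapping RGB channels to source bands.
#' @slot bounds list of per-band normalization bounds.
#' @exportClass CompositeImage
setClass("CompositeImage",
  representation(rgb = "array", provenance = "list", bounds = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "rgb must be a (row, col, 3) array")
    if (min(object@rgb) < 0 || max(object@rgb) > 1)
      msg <- c(msg, "rgb values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })
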