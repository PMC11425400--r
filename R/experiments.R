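## Canned recovery experiments: fixed, seeded study designs that exercise
## the full pipeline (simulate -> mask -> Z-normalize -> wavelet residual
## -> detect -> estimate) under the conditions the package is validated
## against. Encoding them as functions keeps the unit tests, the
## acceptance checks and any user replication on exactly the same design.

#' Two-ROI transport-velocity recovery experiment
#'
#' Simulates one straight SWIR vessel (true width 0.22 mm, depth 1 mm)
#' carrying three boluses at a known velocity, imaged at 10 frames/s on a
#' 0.1 mm/px grid, with circular ROIs 14 mm apart on the vessel. Bolus
#' cadence is set to exceed the ROI-to-ROI transit time so consecutive
#' transits do not interleave at the downstream ROI. The full temporal
#' pipeline is applied and the velocity estimated by greedy event
#' matching.
#'
#' @param trueVelocity simulated bolus velocity, mm/s.
#' @param seed integer seed.
#' @return A list: \code{estimate} (a \code{\link{VelocityEstimate}}),
#'   \code{trueVelocity}, \code{events1}, \code{events2}.
#' @examples
#' ex <- velocityRecoveryExperiment(5, seed = 1)
#' ex$estimate
#' @export
velocityRecoveryExperiment <- function(trueVelocity, seed) {
  pitch <- 0.1
  vessel <- VesselSpec(rbind(c(0, 1.2), c(18, 1.2)), trueWidth = 0.22,
                       depth = 1, peakIntensity = 3000)
  spacing <- 16 / trueVelocity + 1
  starts <- 0.5 + (0:2) * spacing
  train <- BolusTrain(velocity = trueVelocity, startTimes = starts,
                      bolusLength = 2)
  duration <- starts[3] + 16 / trueVelocity + 1.5
  cam <- CameraModel("SWIR", rows = 24, cols = 180)
  sim <- simulateLymphStack(vessel, train, ScatteringModel(), cam,
                            duration = duration, pixelPitch = pitch,
                            frameInterval = 0.1, seed = seed)
  roi1 <- circleMask(24, 180, c(20, 12), 2.5)   # x = 2 mm
  roi2 <- circleMask(24, 180, c(160, 12), 2.5)  # x = 16 mm
  both <- PixelMask(roi1@mask | roi2@mask)
  tsm <- waveletResidualTransform(zNormalizeRows(
    stackToMatrix(sim$stack, both)))
  proc <- matrixToStack(tsm, both, pixelPitch = pitch)
  e1 <- detectBolusPeaks(roiTimeSeries(proc, roi1), 0.1, roiId = "roi1")
  e2 <- detectBolusPeaks(roiTimeSeries(proc, roi2), 0.1, roiId = "roi2")
  list(estimate = transportVelocity(e1, e2, path = 14),
       trueVelocity = trueVelocity, events1 = e1, events2 = e2,
       truth = sim$truth)
}

#' Bolus count-recovery experiment
#'
#' Simulates one straight SWIR vessel carrying five boluses at 7 mm/s with
#' a 2 s cadence, at a signal level chosen so the per-pixel bolus
#' signal-to-noise ratio is about 6 (amplitude over baseline noise sd,
#' median across vessel-core pixels), and counts the events detected in a
#' circular ROI refined by pixel intensity. The event separation floor is
#' half the bolus cadence.
#'
#' @param seed integer seed.
#' @param peakIntensity vessel signal, counts; 60 gives the default
#'   SNR-of-about-6 condition on the SWIR background.
#' @return A list: \code{nDetected}, \code{nTrue}, \code{snr} (measured
#'   per-pixel), \code{events}.
#' @examples
#' bolusCountExperiment(seed = 1)$nDetected
#' @export
bolusCountExperiment <- function(seed, peakIntensity = 60) {
  pitch <- 0.1
  vessel <- VesselSpec(rbind(c(0, 0.8), c(10, 0.8)), trueWidth = 0.22,
                       depth = 1, peakIntensity = peakIntensity)
  train <- BolusTrain(velocity = 7, startTimes = 0.5 + (0:4) * 2,
                      bolusLength = 2)
  cam <- CameraModel("SWIR", rows = 16, cols = 100)
  sim <- simulateLymphStack(vessel, train, ScatteringModel(), cam,
                            duration = 11, pixelPitch = pitch,
                            frameInterval = 0.1, seed = seed)
  roi <- intensityMask(sim$stack, within = circleMask(16, 100, c(50, 8), 2.5))
  m <- tsValues(stackToMatrix(sim$stack, roi))
  snr <- median(apply(m, 1, function(r)
    (max(r) - median(r)) / sd(r[r < quantile(r, 0.6)])))
  tsm <- waveletResidualTransform(zNormalizeRows(
    stackToMatrix(sim$stack, roi)))
  proc <- matrixToStack(tsm, roi, pixelPitch = pitch)
  ev <- detectBolusPeaks(roiTimeSeries(proc, roi), 0.1, minSeparationS = 1)
  list(nDetected = nrow(ev), nTrue = 5L, snr = snr, events = ev)
}

#' Dual-band comparison on one synthetic two-vessel scene
#'
#' Renders the same two-vessel scene (parallel vessels 1.2 mm apart at
#' 3 mm depth) in NIR and SWIR with the default scattering model, draws
#' one line across both vessels, and computes the architectural metrics
#' per band plus their SWIR/NIR ratios. With the default model (more blur
#' and more background in NIR-I) the resolution ratio is below 1 and the
#' distinguishability ratio above 1.
#'
#' @param seed integer seed.
#' @param depth vessel depth, mm.
#' @param noise apply sensor noise.
#' @return A list: \code{metrics} (per band), \code{ratios} (from
#'   \code{\link{compareChannels}}, SWIR over NIR).
#' @examples
#' bandComparisonExperiment(seed = 1)$ratios$distinguishabilityRatio
#' @export
bandComparisonExperiment <- function(seed, depth = 3, noise = TRUE) {
  pitch <- 0.1
  rows <- 80L; cols <- 120L
  vessels <- list(
    VesselSpec(rbind(c(0, 3.4), c(12, 3.4)), trueWidth = 0.22,
               depth = depth, peakIntensity = 20000),
    VesselSpec(rbind(c(0, 4.6), c(12, 4.6)), trueWidth = 0.22,
               depth = depth, peakIntensity = 14000))
  line <- rbind(c(60, 8), c(60, 72))  # vertical line across both vessels
  sc <- ScatteringModel()
  metrics <- lapply(c(SWIR = "SWIR", NIR = "NIR"), function(bandName) {
    cam <- CameraModel(bandName, rows = rows, cols = cols)
    sim <- simulateLymphStack(vessels, NULL, sc, cam, duration = 0.1,
                              pixelPitch = pitch, frameInterval = 0.1,
                              baselineFraction = 1, seed = seed,
                              noise = noise)
    bgFrame <- matrix(unname(sc@backgroundLevel[bandName]), rows, cols)
    prof <- extractProfile(sim$stack, line, backgroundFrame = bgFrame)
    peaks <- findProfilePeaks(prof)
    vesselMetrics(prof, peaks, lineLengthCm = lineLengthCm(line, pitch),
                  band = bandName)
  })
  list(metrics = metrics,
       ratios = compareChannels(metrics$SWIR, metrics$NIR))
}

#' Capillary-phantom depth series
#'
#' Simulates the capillary-tube phantom at the given depths in one band
#' and measures the cross-section FWHM at each depth.
#'
#' @param bandName \code{"NIR"} or \code{"SWIR"}.
#' @param depths depths, mm.
#' @param seed integer seed.
#' @param trueWidth tube width, mm.
#' @param noise apply sensor noise.
#' @return Numeric vector of FWHM (mm), one per depth.
#' @examples
#' phantomDepthExperiment("SWIR", c(0, 5), seed = 1)
#' @export
phantomDepthExperiment <- function(bandName, depths, seed, trueWidth = 1,
                                   noise = TRUE) {
  pitch <- 0.1
  rows <- 128L; cols <- 128L
  vessel <- VesselSpec(rbind(c(6.35, 0), c(6.35, 12.7)),
                       trueWidth = trueWidth, peakIntensity = 30000)
  sc <- ScatteringModel()
  cam <- CameraModel(bandName, rows = rows, cols = cols)
  ph <- simulateCapillaryPhantom(vessel, sc, cam, depths = depths,
                                 pixelPitch = pitch, seed = seed,
                                 noise = noise)
  bgFrame <- matrix(unname(sc@backgroundLevel[bandName]), rows, cols)
  line <- rbind(c(10, 64), c(117, 64))
  vapply(ph$stacks, function(st) {
    prof <- extractProfile(st, line, backgroundFrame = bgFrame)
    peaks <- findProfilePeaks(prof)
    fw <- resolutionFWHM(prof, peaks)
    fw[which.max(peakTable(peaks)$height)]
  }, numeric(1))
}
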