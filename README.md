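# lymphoscope

Quantification of lymphatic vessel architecture and function from dynamic
dual-band fluorescence lymphangiography.

The lymphatic system moves lymph by intrinsic peristaltic contraction:
discrete boluses travel along subsurface vessels and, at a fixed region of
interest (ROI), appear as transient intensity peaks in a fluorescence
image stream. Imaging in the shortwave infrared (SWIR, 900–1800 nm)
suffers less tissue scattering and autofluorescence than the conventional
first near-infrared window (NIR-I, 700–900 nm), so SWIR frames resolve
vessels more sharply. `lymphoscope` provides the analysis that turns such
image stacks into numbers, plus a seeded simulator that generates
dual-band stacks with known ground truth for validation.

## What it computes

**Architecture.** On a line drawn across vessels in a normalized,
background-subtracted frame, peaks are detected with topographic
prominences *p&#7522;* and the package reports

- vessel distinguishability
  *D* = Σ&#7522; *p&#7522;* / (*n* / *L*), with *n* the number of detected
  vessel peaks and *L* the drawn-line length in cm (so the denominator is
  a vessel density per cm), and
- resolution, the full width at half maximum (FWHM) of each vessel peak,
  in mm.

**Function.** Per-pixel time series inside a mask are unrolled to a
(pixel × time) matrix, Z-normalized row-wise (mean 0, population sd 1),
denoised with an eighth-level symlet-8 wavelet transform using
empirical-Bayes posterior-median shrinkage, and reduced to
(denoised − coarse-scale baseline)², a nonnegative series in which each
transiting bolus is a sharp peak. Matching bolus events between two ROIs
a known arclength apart yields the transport velocity
*v* = distance / Δ*t* per bolus, reported as mean ± sd.

**Simulation.** Vessels are tubes of known width (default 0.22 mm, the
anatomical lymphatic diameter measured post-mortem with Evan's blue)
blurred by a depth- and band-dependent Gaussian scattering PSF, with
band-dependent background and Poisson–Gaussian 16-bit sensor noise;
boluses are Gaussian packets advected at a set velocity (default 7 mm/s,
the in vivo regime). Ground truth (geometry, arrival times, seed) is
recorded for recovery experiments.

## Worked example

Simulate one SWIR vessel carrying three boluses at 7 mm/s, run the
temporal pipeline, and estimate the velocity from two ROIs 14 mm apart:

```r
library(lymphoscope)

vessel <- VesselSpec(rbind(c(0, 1.2), c(18, 1.2)), trueWidth = 0.22,
                     depth = 1, peakIntensity = 3000)
train  <- BolusTrain(velocity = 7, startTimes = c(0.5, 4.0, 7.5),
                     bolusLength = 2)
cam    <- CameraModel("SWIR", rows = 24, cols = 180)
sim    <- simulateLymphStack(vessel, train, ScatteringModel(), cam,
                             duration = 11, seed = 42)
sim$stack
#> ImageStack: 24 x 180 pixels, 110 frame(s), band SWIR
#>   pixel pitch 0.1 mm/px, frame interval 0.1 s, 16-bit

roi1 <- circleMask(24, 180, c(20, 12), 2.5)    # x = 2 mm
roi2 <- circleMask(24, 180, c(160, 12), 2.5)   # x = 16 mm
both <- PixelMask(maskMatrix(roi1) | maskMatrix(roi2))
proc <- matrixToStack(
  waveletResidualTransform(zNormalizeRows(stackToMatrix(sim$stack, both))),
  both)
e1 <- detectBolusPeaks(roiTimeSeries(proc, roi1), 0.1, roiId = "roi1")
e2 <- detectBolusPeaks(roiTimeSeries(proc, roi2), 0.1, roiId = "roi2")
e1
#>   roi_id frame time_s    value prominence boundary
#> 1   roi1     8    0.8 12.26124   12.16801    FALSE
#> 2   roi1    43    4.3 14.74060   14.67832    FALSE
#> 3   roi1    78    7.8 13.33599   13.30793    FALSE
transportVelocity(e1, e2, path = 14)
#> VelocityEstimate: 7.000 +/- 0.000 mm/s over 3 pair(s), path 14.00 mm
```

The three upstream events sit within one frame of the true arrival times
(boluses enter at 0.5, 4.0 and 7.5 s and reach the ROI at x = 2 mm about
0.29 s later), and each matched pair gives 14 mm / 2.0 s = 7 mm/s.

Architectural metrics on the same synthetic two-vessel scene rendered in
both bands, with their SWIR/NIR ratios:

```r
bc <- bandComparisonExperiment(seed = 1)
bc$metrics$SWIR
#> VesselMetrics [SWIR]: distinguishability 0.535 (2 vessel(s) on 0.640 cm)
#>   resolution 0.469 +/- 0.005 mm
bc$metrics$NIR
#> VesselMetrics [NIR]: distinguishability 0.399 (2 vessel(s) on 0.640 cm)
#>   resolution 0.928 +/- NA mm
bc$ratios$distinguishabilityRatio   # 1.34  (> 1: SWIR separates better)
bc$ratios$resolutionRatioMean       # 0.50  (< 1: SWIR is sharper)
```

The NIR frame, blurred by twice the PSF of SWIR at equal depth, yields
broader peaks with smaller prominences; one NIR peak's FWHM is flagged
`NA` because its half-maximum crossing is not bracketed before the
neighboring peak — undefined ratios are reported as `NA`, never errors.

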