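---
title: "Quantifying lymphatic architecture and transport from dual-band fluorescence stacks"
author: "lymphoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lymphatic architecture and transport from dual-band fluorescence stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphoscope)
```

# The measurement problem

Fluorescence lymphangiography injects a contrast agent (indocyanine green
in the NIR-I window, or SWIR-emitting probes such as silver sulfide
quantum dots) into the interstitium and films its transport through
subsurface lymphatic vessels. Two kinds of quantity are wanted from such
a stream:

* **architecture** — how many vessels a drawn line crosses, how cleanly
  they separate, and how wide they appear; and
* **function** — when each peristaltically driven bolus of lymph passes a
  region of interest (ROI), and how fast it travels between two ROIs on
  the same vessel.

Both are confounded by tissue scattering: photons emitted at depth reach
the sensor laterally displaced, so a vessel's fluorescent cross-section
is far wider than its anatomical diameter and neighboring vessels blur
together. Scattering (and tissue autofluorescence) is weaker at SWIR
wavelengths than in NIR-I, which is the contrast this package is built to
quantify.

# Architectural statistics

A user draws a polyline across the vessels of interest on a single
frame. `extractProfile()` samples the frame by bilinear interpolation at
points spaced one pixel pitch apart along the line (sampling finer than
the sensor grid would invent detail), subtracts a pre-contrast background
frame sampled identically (flooring at zero), and divides by the profile
maximum so intensities become fractions of the brightest vessel.

`findProfilePeaks()` detects local maxima and assigns each its
**topographic prominence**: the height above the higher of the two key
saddles, where each saddle is the minimum between the peak and the
nearest strictly higher sample on that side, or the signal edge when none
exists. On a profile of up to 200 samples this implementation agrees
exactly with an exhaustive brute-force search over separating minima (a
standing test). Two statistics follow:

* **Vessel distinguishability** \(D = \sum_i p_i \,/\, (n / L_{cm})\):
  summed prominences divided by the vessel density per centimetre of the
  drawn line. The denominator is a density, so a longer line crossing the
  same peaks gives a larger \(D\); the formula is implemented exactly as
  stated, without re-normalizing by line length.
* **Resolution**: the full width at half maximum (FWHM) of each peak,
  found by walking outward from the apex to the two crossings of the
  reference level, each located by linear interpolation between samples.

## Peak-finder parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `minProminence` | 0.05 | fraction of profile max | drops ripple on normalized profiles while keeping faint vessels |
| `minSeparation` | 0.3 | mm | about the apparent width of the narrowest resolvable vessel; closer maxima are one vessel |
| `refLevel` | `"height"` | — | background-subtracted profiles have baseline ≈ 0, so half height is the natural FWHM level; `"prominence"` (height − prominence/2) is available for heavily overlapped peaks |

These play the role of the "empirically tuned" settings any practitioner
supplies to a peak finder; they are configuration, recorded in the
`PeakSet`, and no claim is made that they match any particular prior
study. Tie-breaks and degenerate cases: a plateau maximum is reported at
its leftmost sample; when peaks are closer than `minSeparation` the
taller is kept; an FWHM is `NA` when a crossing is not reached before the
profile edge or before terrain rises above the apex (unresolved overlap);
an all-zero profile under normalization is returned as zeros and flagged
degenerate. Band comparisons (`compareChannels()`) report
`NA` — never an error — for ratios with a zero denominator or when the
two bands detected different peak counts.

# The temporal transform

Raw ROI series are dominated by slow contrast kinetics and pixel noise,
which bias naive peak picking. The package applies a five-step transform:

1. **Mask** pixels of interest (hand-drawn circles/polygons via
   `circleMask()`/`readRoiJson()`, optionally refined by pixel intensity
   with `intensityMask()` — background pixels contribute only noise).
2. **Unroll** the stack to a (pixel × time) matrix (`stackToMatrix()`;
   the mask mapping is a bijection and `matrixToStack()` inverts it
   exactly) and **Z-normalize** each row: subtract the row mean, divide
   by the row standard deviation. The *population* convention (divide by
   \(n\)) is used, fixed by the two-point convention that `c(0, 1)` maps
   to `c(-1, 1)`; constant rows map to zero and are flagged.
3. **Denoise** each row by a discrete wavelet transform in the symlet-8
   family at decomposition level 8 (capped at
   \(\lfloor\log_2 n\rfloor - 1\) for short series, with the level
   actually used recorded in metadata). Detail coefficients are shrunk by
   the empirical-Bayes posterior median under a spike-and-Laplace prior,
   with the mixing weight estimated per level by marginal maximum
   likelihood and a single per-row noise scale — the median absolute
   finest-level detail divided by 0.6745 — shared across levels
   (level-independent noise estimation).
4. **Subtract the baseline and square.** The baseline is the inverse
   transform of only the final-level approximation (scaling)
   coefficients, all detail bands zeroed — a smooth curve carrying the
   slow kinetics. The output is (denoised − baseline)², elementwise:
   nonnegative by construction, near zero wherever the series is smooth,
   and sharply peaked at transient bolus transits. Reading "reconstruction
   from the scaling coefficients" as the detail-free inverse transform is
   the central interpretive decision of this module; it is what makes the
   residual isolate transients.
5. **Refold** to a stack, so ROIs can be averaged and events detected
   per ROI.

## Wavelet implementation notes

No wavelet package is part of the dependency set, so the filter bank is
implemented in the package using the published 16-tap orthonormal
symlet-8 pair. The transform is periodized (exact reconstruction for any
even length; verified to 1e-9 in tests). Boundaries are handled by
reflect-padding each row to the next multiple of \(2^{level}\) and then
mirroring the whole padded row, which makes the periodic extension
continuous at both junctions; the result is cropped back to the original
length. Derivative kinks at the mirror junctions still generate small
boundary detail coefficients — one reason `detectBolusPeaks()` flags
events within 8 frames of either end as `boundary`. "Eighth-level symlet"
is ambiguous between wavelet order and decomposition depth; both default
to 8 and are independently configurable in `WaveletParams`.

The shrinkage follows the Johnstone–Silverman posterior-median rule
(Laplace scale \(a = 0.5\)), with Mills-ratio forms for numerical
stability and a hard fallback to the no-shrinkage limit for standardized
coefficients beyond ±25, where the posterior is effectively centred on
the observation. Rows whose finest-level details are all zero (noise
estimate 0) pass through unshrunken.

# Bolus events and transport velocity

`detectBolusPeaks()` applies the same prominence rule to the time axis;
event times are frame index × frame interval with 0-based frames. The
default prominence floor is a quarter of the series range — calibrated on
simulated transits, where residual-squared noise spikes stay well below
that fraction while genuine transits exceed half the range — and the
default separation floor is 0.5 s (1 s in the canned count-recovery
design, half its 2 s bolus cadence).

`transportVelocity()` matches events greedily: each upstream event pairs
with the earliest unused downstream event strictly after it and before
the next upstream event. Each pair gives velocity = path arclength / Δt;
the estimate is the mean ± sd over pairs, with unmatched events reported.
The matching rule is a design choice (the field's descriptions leave it
open); `velocityByCrossCorrelation()` provides an independent lag-based
cross-check. Degenerate cases return flagged empty estimates, not
errors. Note the design implication: the matching window closes at the
next upstream event, so the experiment (or the vessel) must deliver
boluses at a cadence longer than the ROI-to-ROI transit time — the canned
velocity experiment sets its cadence to transit time + 1 s for exactly
this reason.

# What the simulator emulates — and what it does not

`simulateLymphStack()` and `simulateCapillaryPhantom()` generate the
structures the analysis assumes:

* **Geometry**: vessels as polyline-centred tubes of true width 0.22 mm
  (the anatomical diameter measured post-mortem with Evan's blue dye),
  rendered with linear-ramp pixel coverage so that an unblurred
  cross-section's half-maximum crossings fall exactly at ±width/2.
* **Scattering**: an isotropic Gaussian PSF whose sigma grows linearly
  with depth, by default 0.12 mm/mm in NIR-I and 0.06 mm/mm in SWIR.
  Real tissue PSFs are not Gaussian and not linear in depth; the linear
  Gaussian is the simplest model reproducing the qualitative phantom
  behaviour (monotone widening with depth, NIR wider than SWIR), and the
  rates are configuration, not physics. Consequently the package asserts
  the *direction* of width inflation (apparent FWHM > 0.22 mm under any
  nonzero blur, growing with blur) but never a specific inflation factor
  such as the ~5× reported in vivo, which depends on the unknown tissue
  PSF.
* **Background**: spatially uniform per band, by default 300 counts
  (NIR-I) and 60 (SWIR), encoding the higher NIR autofluorescence; real
  autofluorescence is heterogeneous.
* **Boluses**: 1-D Gaussian packets in arclength (FWHM = `bolusLength`,
  default 2 mm) advected at constant velocity (default 7 mm/s, within
  the 6.4–7.1 mm/s range observed in vivo), over a resting baseline
  vessel signal (default 25% of peak). Real boluses disperse and
  vessels pump irregularly.
* **Sensor**: Poisson shot noise plus Gaussian read noise (sd 10
  counts), clipped to 16 bits; camera geometries default to 512×512
  (NIR-I intensified CCD) and 512×640 (SWIR InGaAs). The frame interval
  defaults to 0.1 s — "video rate" acquisition is not standardized, and
  10 frames/s makes a 7 mm/s bolus advance 0.7 mm/frame, resolvable on
  the default 0.1 mm/px grid.

Pixel indices are 0-based in physical conversions (position = index ×
pitch), and identical configuration + seed reproduces stacks
bit-identically. Because the generator shares none of the analysis code
path (rendering is geometric; detection is signal-processing), recovery
tests are meaningful — but they validate the pipeline *under this
model*: passing them says nothing about non-Gaussian PSFs, motion,
photobleaching, or clearance kinetics, which are out of scope.

# Validation designs and problem sizes

The canned experiments (exported, so tests and the acceptance script run
the same design) were sized to exercise the estimators without waste:

* *Velocity recovery*: one straight vessel, ROIs 14 mm apart on a
  0.1 mm/px grid at 10 frames/s, three boluses per run, velocities 2, 5
  and 10 mm/s, 20 seeds each; the mean recovered velocity must fall
  within 10% of truth (frame quantization alone contributes up to
  ±0.05 s on transits of 1.4–7 s).
* *Count recovery*: five boluses at 2 s cadence with vessel intensity
  set so the per-pixel bolus SNR is ≈ 6 (median bolus amplitude over
  baseline noise sd across vessel-core pixels); 100 seeds; at least 95
  runs must detect exactly five events. Below SNR ≈ 5.5 the exact-count
  rate degrades as single-frame noise spikes survive shrinkage — the
  package reports the measured SNR alongside the count for this reason.
* *Band comparison*: two parallel 0.22 mm vessels 1.2 mm apart at 3 mm
  depth, rendered in both bands from the same seed. At this depth the
  NIR PSF (σ = 0.36 mm) partially merges the pair while SWIR
  (σ = 0.18 mm) resolves it, so the distinguishability ratio (SWIR/NIR)
  exceeds 1 and the resolution ratio falls below 1; only these
  directions are asserted, not magnitudes.
* *Phantom depth series*: a 1 mm capillary tube at 0, 5 and 10 mm depth
  in each band; FWHM must be nondecreasing in depth and smaller in SWIR
  at nonzero depth.

# Known limitations

* The PSF model is phenomenological; blur rates must be calibrated
  against phantom data before simulator widths can be compared with a
  real rig.
* Vessel segmentation and centerline tracing are out of scope: lines,
  ROIs and paths are user input, as in manual practice.
* The residual transform assumes bolus transits are fast relative to the
  level-8 baseline scale; extremely slow transits (many hundreds of
  frames) would be absorbed into the baseline.
* Event matching assumes bolus cadence exceeds the inter-ROI transit
  time; when it does not, the cross-correlation estimator is the
  appropriate fallback.
* Image co-registration between bands is the caller's responsibility;
  `overlayChannels()` (NIR purple, SWIR green, overlap white) assumes
  pre-aligned frames.
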