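Package: lymphoscope
Title: Quantification of Dual-Band NIR/SWIR Fluorescence Lymphangiography
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify lymphatic vessel architecture and function from
    dynamic near-infrared (NIR-I) and shortwave-infrared (SWIR) fluorescence
    image stacks. Implements vessel cross-section profiling with topographic
    peak prominences, the vessel-distinguishability statistic (summed peak
    prominences per vessel density along a drawn line), full-width-at-half-
    maximum resolution measurement, a Z-normalization and symlet-wavelet
    residual transform of per-pixel time series for lymph-bolus detection,
    and two-ROI bolus transport-velocity estimation. A seeded synthetic-data
    module simulates dual-band image stacks (tissue-phantom capillaries and
    in-vivo-like vessel scenes) with depth-dependent Gaussian scattering blur,
    band-dependent autofluorescence background and Poisson-Gaussian sensor
    noise, recording full ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Visualization, CellBiology
RoxygenNote: 7.3.3
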