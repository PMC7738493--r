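Package: poolsi
Title: Pooled Scale Invariance Analysis of V1 Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how receptive-field (RF) tuning in primary
    visual cortex deviates from scale invariance. Implements the closed-form
    scale-invariance and pooled-scale-invariance Gabor model equations that
    relate preferred spatial frequency to RF width, spatial-frequency
    bandwidth, orientation bandwidth and phase selectivity (F1/F0); a
    synthetic-data generator producing cortical functional maps, neuron
    populations, stimulus-triggered response kernels and calcium imaging
    movies; an imaging pipeline (rigid alignment, local cross-correlation
    cell detection, notch filtering, Z-scoring, stimulus-triggered
    averaging); tuning-curve fitting with the associated exclusion rules;
    estimators for the spatial and spectral pooling widths, the absolute
    phase-progression rate and the cortical magnification factor, with
    leave-one-out cross-validated model comparison; and distance-binned
    functional-clustering statistics with shuffle-based significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
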