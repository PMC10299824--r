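Package: mobprox
Title: Chromatin Mobility Classification from Single-Molecule Tracks and
    Proximity-Labeling Interactome Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two quantitative procedures used to study transcription
    factor chromatin occupancy and protein interactions in live cells. The first
    is a two-parameter single-molecule-tracking analysis: per-track time-averaged
    mean squared displacement, anomalous diffusion exponent, confinement radius
    and frame-to-frame jump statistics; threshold classification into confined,
    Brownian and directed motion; detection and segmentation of mixed-mobility
    ("butterfly") tracks; quality filters; seeded down-sampling; and gating of
    the (confinement radius, average displacement) plane into low- and
    high-mobility chromatin regions calibrated on a histone H2B reference. The
    second is a differential interactome caller for TurboID proximity-labeling
    label-free proteomics: contaminant filtering, valid-value filtering,
    left-shifted missing-value imputation, dual-control enrichment testing with
    Benjamini-Hochberg correction, and mean +/- 3 s.d. differential-interactor
    scoring. A synthetic-data module simulates trajectories and intensity
    matrices with known ground truth so every stage is testable end to end.
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
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
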