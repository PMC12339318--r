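Package: flimpipe
Title: Simulation and Analysis of TCSPC Fluorescence Lifetime Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-correlated single photon counting (TCSPC)
    fluorescence lifetime imaging microscopy (FLIM) of stained tissue
    sections. Simulates photon-count image cubes with known lifetime-component
    mixtures, fits per-pixel biexponential decay models by weighted least
    squares to produce amplitude-weighted mean-lifetime maps, performs
    frequency-domain phasor analysis (universal-semicircle geometry,
    calibration, k-means segmentation), and runs the downstream region
    statistics used in quantitative histopathology: quadrant comparison by
    Student t-test, per-sample normalization of cancerous/peritumoral lifetime
    ratios, and Pearson correlation against clinical laboratory indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
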