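Package: massdivide
Title: Dry-Mass Partitioning Analysis for Quantitative Phase Time Lapses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of single-cell dry-mass partitioning during cytokinesis
    from quantitative phase imaging (QPI) time lapses. Provides a seeded
    synthetic phase-movie generator with a full ground-truth ledger,
    classifier-plus-random-walker phase unwrapping with single positive
    wavelength corrections, watershed cell segmentation with dry-mass
    measurement via the specific refractive increment, positional track
    linking, sigmoid matched-filter detection of mitotic entry/exit and
    cell-division events, and daughter-cell mass-asymmetry statistics
    (delta-m dynamics, atan2 heatmap ordering, population coefficient of
    variation, Welch t and regression F tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    MASS,
    Matrix,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
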