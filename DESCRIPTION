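Package: focalmetry
Title: Focal-Volume Metrology and Image-Quality Evaluation for Deep
    Two-Photon Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying two-photon microscope focal volumes and
    image quality as a function of imaging depth and refractive-index
    mismatch. Implements bead-based point-spread-function metrology
    (Gaussian full-width-at-half-maximum fitting of axial and lateral
    intensity profiles), lowest-pixel background and signal estimation,
    Brenner-gradient contrast scoring, extraction of spontaneous calcium
    activity regions by Otsu thresholding with area filtering, and the
    accompanying nonparametric statistics (Welch's t-test with Bonferroni
    correction, Friedman test with Dwass-Steel-Critchlow-Fligner all-pairs
    post-hoc comparisons). A synthetic-data generator produces bead stacks,
    neurite-like structure stacks and calcium movies with known ground
    truth so every stage of the pipeline can be validated without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
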