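Package: stentr
Title: Behavioral State-Field Quantification of Stentor Shape Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the shape-state behavior of the giant ciliate
    Stentor coeruleus from time-lapse recordings in quasi-2D chambers.
    Provides a ground-truthed agent-based behavior simulator and movie
    renderer, background-subtraction segmentation with maximum-entropy and
    triangle thresholding, centroid/radial-profile morphometry, kinematic
    smoothing and normalization, classification of droplet/cone/trumpet
    states on the normalized length-speed state field, transition-vector
    fields and hierarchical clustering of steady states, exponential and
    two-mode relaxation fits of shape-transition kinetics, length-speed
    power-law scaling, rotating-lap diameters, and spatial occupancy and
    adhesion statistics for structured chambers with crescent dead ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
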