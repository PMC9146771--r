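Package: thermofoot
Title: Prior-Shape Active Contours for Plantar Foot Thermal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of plantar-foot infrared thermography images with
    prior-shape active contours (snakes), aimed at diabetic-foot screening.
    Implements a curvature-prior snake in which a normalized curvature
    difference to an average foot shape is added to the classical snake
    energy, together with two comparator prior-shape snakes (a greedy snake
    with normalized Fourier-descriptor shape matching, and a geodesic snake
    with a fast-marching distance prior and similarity-transform descent).
    Includes a seeded synthetic thermal foot phantom generator with ground
    truth, preprocessing (two-feet split, Otsu thresholding, morphological
    cleanup, gravity centers), prior-shape construction and initialization,
    contour RMSE and Dice evaluation with robustness harnesses, and a
    hyperthermia detection pipeline based on point-to-point absolute
    temperature differences between registered feet.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
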