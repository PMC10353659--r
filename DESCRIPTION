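Package: greensim
Title: Simulated Crop Canopy Imagery for Green Fraction Segmentation
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Procedurally generates rice and wheat canopy scenes from a
    Latin-hypercube-sampled parameter space, renders them through a
    pinhole camera to RGB images with pixel-perfect green-vegetation
    masks, tiles them into segmentation datasets, and evaluates
    segmenters at the pixel scale (confusion proportions, accuracy,
    F1, normalized Euclidean domain-gap distance) and the image scale
    (green fraction, R-squared, RMSE). Includes a classical
    excess-green plus Otsu baseline segmenter, adapters for external
    models, and an uncertainty toolkit built on CIELAB lightness and
    excess-green per-pixel features with kernel density estimates per
    error class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    png,
    Rcpp,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    farver,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
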