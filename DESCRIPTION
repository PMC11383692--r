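Package: brightcount
Title: Label-Free Cell Viability from Brightfield Images via Dual
    Count-Regression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the viability of an adherent cell culture from
    unstained brightfield phase-contrast images. Two independent
    convolutional count-regression networks predict, per 224x224 tile, the
    total number of cells (from contrast-stretched tiles) and the number
    of dead cells (from Sobel edge-enhanced tiles, which highlight the
    bright halo and dark core of dying cells); the two counts combine into
    a viability percentage, 100 * (1 - dead/total). Includes a synthetic
    brightfield scene generator with known live/dead composition, readers
    and writers for VGG Image Annotator (VIA) point-label JSON, the tiling
    and enhancement preprocessing, training and evaluation utilities with
    broom-style tidiers and ggplot2 autoplot methods, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
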