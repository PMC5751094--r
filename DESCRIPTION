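Package: planktonmkl
Title: Plankton Image Classification with Multi-View Features and Multiple Kernel Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic plankton image classification toolkit. Grayscale
    plankton images are preprocessed (thresholding, sub-5-pixel marine-snow
    removal, cell extraction) and described by ten complementary feature
    groups: geometric/grayscale measurements, Gabor filter-bank energies,
    variograms, grid local binary patterns, binary gradient contours, two
    morphological granulometry size distributions, histograms of oriented
    gradients, SIFT-style bag-of-visual-words histograms, and inner-distance
    shape context distances to per-class shape templates. Per-group wrapper
    feature selection and a nonlinear multiple kernel learning classifier
    (polynomial combination of linear, polynomial and Gaussian base kernels
    with learned nonnegative weights) combine the views; recall, precision
    and F-measure are reported from confusion matrices under stratified
    cross-validation. A deterministic synthetic plankton image generator
    supports end-to-end experiments without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    kernlab,
    e1071,
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
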