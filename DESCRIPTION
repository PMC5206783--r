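Package: redeye
Title: Automatic Grading of Bulbar Conjunctival Hyperemia from Ocular
    Surface Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective grading of bulbar conjunctival hyperemia
    (ocular redness) on the Efron 0-4 scale from slit-lamp photographs.
    Implements an ensemble of colour-threshold segmentations of the
    conjunctiva, polygon-based regions of interest with a central 512-px
    square and grid subdivisions, 24 colour- and vessel-edge-based
    hyperemia features computed per region, correlation-based (CFS),
    RReliefF and support-vector-weight feature selection with fold
    aggregation, and regression onto clinical grades (multilayer
    perceptron, partial least squares, random forest) evaluated by
    10-fold cross-validated mean squared error.  Ships a synthetic
    ocular-surface scene generator (near-white sclera, curvilinear
    vessels, iris and eyelid occluders, simulated expert graders) so the
    whole pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    png,
    EBImage,
    nnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    tiff,
    jpeg,
    optparse,
    withr
Config/testthat/edition: 3
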