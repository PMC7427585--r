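Package: phenogreen
Title: Multi-Plant Greenhouse Image Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for top-view multi-pot greenhouse
    phenotyping experiments. Generates synthetic greenhouse scenes with exact
    ground truth, locates pots and selects the correct group of ten plants
    using a central QR fiducial, white-balances images against the QR white
    background, segments plants by dual-colorspace (HSV and CIELAB)
    thresholding or a small U-net trained with a deterministic 40-fold
    augmentation scheme, scores segmentations (IoU, Dice, pixel accuracy,
    precision, recall, F1, AP at 0.5 IoU), and converts per-plant observation
    streams into growth and greenness traits (AreaPerDay, RateOfHue) with
    broad-sense heritability from variance components. Includes camera-uptime
    reporting and a concurrency-safe batch pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    parallel,
    EBImage,
    png,
    jsonlite,
    yaml,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
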