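Package: cytomorph
Title: Computational Cytomorphology of Peripheral Blood Smears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection, morphometric characterization and
    disease-association analysis of white and red blood cells in digitized
    peripheral blood smears. Provides tile quality control, white-cell
    segmentation with test-time augmentation and nucleus partitioning,
    classical red-cell candidate detection with a learned morphometric
    filter, a fixed 42/53-dimensional morphometric feature schema,
    slide-level classification from morphometric moments with elastic-net
    logistic regression, and a multiple-instance-learning morphotype model
    that learns soft cell prototypes jointly with per-task linear heads,
    with cross-fold stability selection. A synthetic-data module generates
    smear tiles with ground-truth masks and per-cell feature bags with
    planted morphotype structure so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    glmnet,
    xgboost,
    jsonlite,
    yaml,
    png,
    tiff,
    arrow,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
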