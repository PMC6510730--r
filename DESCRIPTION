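Package: rktree
Title: Growth-Curve Parameter Extraction and Decision-Tree Analysis of
    Media Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links defined culture-media composition to bacterial growth
    phenotypes measured in 96-well plate-reader kinetics. Extracts the
    exponential growth rate (r) and saturated density (K) from OD600 time
    series with a robust multi-step procedure (background subtraction,
    exponential-window selection, log-slope computation, box-plot outlier
    removal), expands compound recipes into ionic/molecular component
    concentrations, fits CART regression trees with k-fold cross-validated
    depth selection and split-stability reports, and classifies decision
    chemicals into trade-off versus uniform mechanisms by comparing
    optimal concentration intervals for fast growth and high density.
    Includes a synthetic plate-data generator with planted decision
    structure so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
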