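Package: kdsense
Title: Colorimetric Urine Sensor-Array Diagnostics for Kawasaki Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for urinary colorimetric sensor-array
    diagnostics of Kawasaki disease versus febrile controls: quantification
    of scanned 384-well plate images into per-compound RGB color-difference
    vectors, urinary creatinine normalization to correct hydration-driven
    dilution, genetic-algorithm wrapper selection of a discriminant compound
    panel scored by cross-validated ROC AUC of a CART-style decision tree,
    and probabilistic decision-tree classification with ROC and contingency
    evaluation. Includes a synthetic-cohort generator with planted
    class-informative compounds and rendered plate scans so every stage can
    be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
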