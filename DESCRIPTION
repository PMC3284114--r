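Package: cbal
Title: Class-Balanced Active Learning for the Minority-Class Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training-set construction for binary classifiers when the target
    class is rare and annotation is expensive. Implements query-by-committee
    active learning with class-ratio-constrained annotation (class-balanced
    active learning), the competing random-learning and unbalanced baselines,
    a negative-binomial model that predicts the annotation cost of class
    balancing, ROC/AUC training-set evaluation, and patch-level texture
    features (first-order, Haralick co-occurrence, Gabor filter bank) for
    histopathology-style image regions. Includes seeded synthetic-data
    generators (imbalanced feature pools and textured image patches) so the
    whole pipeline can be exercised and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    xgboost,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
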