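Package: persohar
Title: Personalized Human Activity Recognition via Incremental Ensemble Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalizes user-independent human activity recognition models from
    streaming inertial-sensor data. Implements a Learn++-style incremental ensemble
    with equal-weight soft voting over linear discriminant analysis, regularized
    quadratic discriminant analysis and classification-tree base models; sliding-window
    segmentation and a time- and frequency-domain feature bank; chunk labeling by
    non-supervised, semi-supervised (dual posterior confidence thresholds with
    two-window label propagation) and supervised policies; noise-injection
    augmentation, bootstrap sampling and sequential forward feature selection for
    base-model training; and a leave-one-subject-out experimental protocol reporting
    balanced accuracy and macro false negative rate after every ensemble update.
    Includes a seeded multi-subject synthetic stream generator with subject-specific
    gain, offset and frequency deviations for controlled personalization studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    rpart,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
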