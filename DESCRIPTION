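Package: skelvar
Title: Movement Quantification from Skeleton Keypoint Sequences for
    Hyperactivity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies restlessness in seated subjects from 2-D pose-estimation
    output (OpenPose BODY_25 keypoints). Converts per-frame skeleton detections
    into bone-length and bone-angle time series, summarizes each series by its
    windowed averaged variance, and assesses how well the resulting descriptors
    separate ADHD from non-ADHD children: per-descriptor Welch t-tests,
    a bootstrap optimal-cutpoint analysis with Youden-index selection and
    out-of-bag evaluation, and a multi-classifier feature-combination ranking
    (AdaBoost, CART, k-nearest neighbors, random forest, RBF support vector
    machine, gradient-boosted trees) under repeated cross-validation and
    holdout resampling. Includes a seeded synthetic cohort generator (skeleton
    level and feature-table level) so the full pipeline is testable without
    clinical videos.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rpart,
    class,
    ranger,
    e1071,
    xgboost,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
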