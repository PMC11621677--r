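Package: dietvision
Title: Passive Dietary Assessment from Egocentric Segmentation Masks and Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates consumed food portion size (grams) from passively
    captured egocentric video frames, downstream of neural perception.
    Provides frame filtering by an edge-region incomplete-container rule,
    container volume estimation via depth re-projection and 3D convex hulls,
    handcrafted portion-size features (food type one-hot, food region ratio,
    container volume, plate pixel count, plate aspect ratio via SVD, and
    area-weight ratio), a stacking ensemble portion regressor with
    volume-weight augmentation, permutation feature importance, tolerance
    accuracy, MAPE and Bland-Altman agreement metrics, and a fully synthetic
    scene generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    randomForest,
    ranger,
    xgboost,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
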