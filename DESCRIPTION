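Package: oodeval
Title: Out-of-Distribution Confidence Scores and Evaluation for Image
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluation pipeline for extrusive out-of-distribution (OOD)
    detection wrapped around a trained classifier. Implements three
    confidence scores (maximum softmax probability, class-conditional
    Mahalanobis confidence with a tied covariance, and the energy score),
    the ID1/ID2/ID3 data-split protocol, ROC-based metrics (AUROC, FPR at
    95% TPR, Youden threshold selection, accuracy at a threshold), and
    three experiment axes: classifier accuracy, degree of
    out-of-domainness, and class imbalance of the detector-fitting set.
    Includes a synthetic-data generator producing class-conditional
    Gaussian features, mean-shifted OOD samples at a controllable
    distance, class-size profiles, and toy raster images, so the full
    pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
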