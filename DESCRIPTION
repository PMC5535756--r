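Package: ccvnuclei
Title: Nucleus Patch Classification with Sparse-Contribution Feature
    Selection and Concave-Convex Variation Classifier Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 64x64 single-nucleus image patches
    (normal versus abnormal hepatocellular carcinoma cells) from
    hand-crafted intensity, morphology and texture features.  Provides a
    synthetic patch generator emulating segmented H&E nuclei, bilateral
    filtering and Moore-neighbour contour tracing, a feature bank (summary
    statistics, region morphology, grey-level co-occurrence, local binary
    patterns, SIFT keypoint aggregates, Tamura statistics), a
    sparse-contribution filter feature-selection model based on unit-circle
    contribution scoring, three probability-emitting base classifiers
    (an extreme learning machine fitted by Moore-Penrose pseudoinverse,
    support vector machine, random forest), and a concave-convex variation
    statistic of the nucleus contour used to reweight classifier
    posteriors.  Includes evaluation metrics, PR/ROC curves and an
    experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    grDevices,
    jsonlite,
    png,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
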