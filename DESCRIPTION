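Package: metricqsar
Title: Vector-Space and Metric-Space QSAR Modeling with Representation Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for quantitative structure-activity relationship
    (QSAR) regression that represents molecules either in vector space
    (molecular descriptors and fingerprint bits, reduced by random-forest
    feature ranking or principal component analysis) or in metric space
    (Tanimoto similarity profiles reduced by PCA with out-of-sample
    projection). Activities are curated Ki values mapped to a clamped,
    scaled pKi in [0, 1]. Models are support vector regressions whose
    dimensionality is chosen by feedforward cross-validation; competing
    representations are compared across datasets with the Friedman rank
    test and Conover post hoc letter groupings. Includes a nearest-neighbor
    pruning experiment for redundancy-robustness analysis and a synthetic
    structure-activity generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
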