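Package: offTargetBelief
Title: Off-Target Activity Prediction by Fusing Similarity and
    Machine-Learning Beliefs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the likelihood that a query molecule is active
    (IC50 <= 100 nM) against off-target safety-panel proteins. A
    similarity-derived belief is obtained by evaluating a sigmoid
    probability-assignment curve at the highest extended-connectivity
    fingerprint (ECFP) Tanimoto similarity between the query and a
    library of known actives; a second belief comes from a calibrated
    per-target machine-learning classifier trained on 2D descriptors.
    The two beliefs are fused with Hooper's rule, gated by a
    similarity-based applicability domain, and reported together with
    the nearest active neighbor. Includes dataset curation, compound
    pair construction and curve fitting, model training and selection
    by Matthews correlation coefficient under repeated stratified
    cross-validation, probability calibration (Platt, isotonic,
    logistic stacking), and a synthetic-data generator for end-to-end
    testing without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    minpack.lm,
    jsonlite,
    ranger,
    xgboost,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
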