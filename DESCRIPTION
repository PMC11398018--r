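Package: pdspeech
Title: Cross-Corpus Speech-Embedding Analysis and Feature-Overlap Testing
    for Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-pooled speech-embedding features in
    Parkinson's disease voice studies: energy-threshold loud-region
    segmentation of raw audio, fixed-vector feature construction from
    frame-level embeddings (mean/std/sum pooling, MFCC means, PCA combo
    vectors), repeated stratified cross-validated and cross-corpus
    classification and regression harnesses, per-feature global importance
    via standardized logistic coefficients, Monte-Carlo Shapley attribution
    and impurity scores, and an exact hypergeometric (one-sided Fisher)
    test with Monte-Carlo null and Bonferroni correction for the overlap
    between top-k important-feature sets of different models. A synthetic
    cohort generator with planted discriminative channels makes the whole
    pipeline testable without any speech corpus or pretrained model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    zoo,
    glmnet,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
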