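Package: pathsig
Title: Individualized Pathway Scoring and Longitudinal Analysis of Blood Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sample pathway activity scoring of bulk RNA-seq with the
    rank-exponential FAIME statistic, robust differential-pathway analysis
    (winsorized Yuen test and the dR robust effect size with a dual
    FDR/effect-size significance rule), Ward clustering of sample pathway
    profiles, repeated and nested cross-validated classification with
    in-fold feature selection, and an ANCOVA change method for paired
    baseline/follow-up designs. Includes a negative-binomial synthetic
    cohort generator with a known ground truth so the whole pipeline is
    testable without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
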