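Package: crfvoter
Title: Stacked Conditional Random Field Ensembles for Biomedical Named
    Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for gene- and protein-related named entity recognition
    cast as IOB2 sequence labeling. Provides CoNLL-style TSV corpus
    input/output with span/tag conversion and document-level splitting, a
    configurable sparse feature-template engine, a linear-chain
    conditional random field with exact forward-backward inference,
    Viterbi decoding and L1/L2-penalized maximum-likelihood training,
    hyperparameter search by exhaustive grid, random sampling or a
    tree-structured Parzen estimator, a positionwise majority-vote
    baseline and a two-stage stacked CRF ensemble in which base-learner
    output labels become second-level features, entity-level
    precision/recall/F1 scoring with McNemar significance testing, and a
    seeded generator of synthetic annotated corpora and simulated
    labeler outputs with controllable complementary error structure.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
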