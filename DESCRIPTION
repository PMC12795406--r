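Package: rolepred
Title: Incremental Semantic Role Predictability in Child-Directed Speech
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how predictable agent (A) and patient (P)
    roles are at each position of an utterance, under strictly incremental
    processing. Provides a data model for role-annotated utterance corpora,
    seeded generators for artificial-language corpora emulating verb-initial
    (symmetrical voice), verb-medial (rigid order) and verb-final
    (case-marking, frequent agent omission) archetypes, an incremental
    recurrent semantic role prediction model (LSTM sentence processor with a
    sequential argument encoder, role classifier and next-word predictor,
    trained in a pretraining and a joint main stage, evaluated by k-fold
    cross-validation), extraction of position-conditioned predictability
    records, and hierarchical Bayesian beta regression of role predictability
    on sentence position, role and language with NUTS sampling, convergence
    diagnostics, PSIS-LOO model comparison and stacking weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
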