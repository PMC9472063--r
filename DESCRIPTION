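Package: phideid
Title: Deidentification of Protected Health Information by Sequence Tagging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protected health information (PHI) deidentification for clinical
    text, cast as named-entity recognition over four PHI categories (personal
    names, locations, organizations, dates). Provides a linear-chain
    conditional random field (CRF) prediction head with exact forward
    log-partition, gradients and constrained Viterbi decoding over BIO tag
    sequences; a compact multi-head self-attention encoder producing CRF
    emission scores; transformer-layer knowledge distillation from a larger
    teacher encoder to a small student; a hybrid data-augmentation engine
    combining generation-based augmentation (linearized label/token language
    modelling) with mention replacement; a seeded synthetic-corpus generator
    emulating a 4-type PHI corpus; entity-level precision/recall/F1
    evaluation; and pipeline utilities for training, prediction, surrogate
    replacement and annotation bootstrapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
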