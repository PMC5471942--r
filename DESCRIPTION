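Package: tieredatc
Title: Tiered Learning for Anatomical Therapeutic Chemical Code Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical (tiered) classification of compounds into WHO
    Anatomical Therapeutic Chemical (ATC) codes. A dedicated classifier
    instance is trained for every ATC prefix so that the predicted code at
    each level selects the classifier that refines the next level, seeded
    either by a supervised level-1 classifier or by an external level-1
    mapping. Includes the compound descriptors used for this task (hashed
    linear-path and Morgan chemical fingerprints, chemical-interaction
    profiles and chemical-target profiles built from STITCH-style
    association tables), a flat per-level baseline, per-level, cumulative
    and path-correct accuracy measures with stratified cross-validation and
    a random-label control, and a synthetic-benchmark generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    yaml,
    e1071,
    nnet,
    randomForest,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
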