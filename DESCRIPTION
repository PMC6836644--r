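Package: mcscreen
Title: Measure-Guided Multiple Classifier Systems for Ligand-Based Virtual
    Screening
Version: 0.1.0
Authors@R:
    person("mcscreen", "developers", email = "mcscreen@example.org",
           role = c("aut", "cre"))
Description: Ligand-based virtual screening with multiple classifier
    systems. Feature columns (circular-fingerprint bits and
    physicochemical descriptors) are grouped into clusters by Fisher
    score, one classifier per cluster is selected by cross-validation
    against a chosen objective (Matthews correlation coefficient or
    positive predictive value), and the per-cluster predictions are
    combined by voting. Two measure-optimized models compose
    false-positive-minimizing (AND) and false-negative-minimizing (OR)
    meta-models. Predicted actives are ranked by the product of their
    inner-classifier activity probabilities and diversified by
    Tanimoto-distance leader clustering. Includes a synthetic compound
    table generator, pharmacology helpers (Cheng-Prusoff Ki, pKi,
    percent specific binding), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    FNN,
    glmnet,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
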