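Package: bnmmi
Title: Bayesian Network-Based Missing Mechanism Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies the missing-data mechanism of a dataset with one
    incompletely observed categorical variable by learning the Bayesian
    network over the missing indicator and the fully observed variables
    (score-based hill climbing from the empty graph), assessing the
    credibility of the learned structure by nonparametric bootstrap and
    against an expert-specified structure, and classifying the mechanism
    as missing completely at random (MCAR), not-MCAR (MAR or MNAR), or
    inconclusive. Includes the clinical chain simulator
    (tumour type -> operation -> two-week discharge) used to calibrate
    the method, a logistic-regression comparator, and the validity /
    consistency / robustness performance measures for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
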