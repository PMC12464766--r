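Package: ADquadrant
Title: Quadrant-Aligned Featurization and Enantioselectivity Modeling for the
    Sharpless Asymmetric Dihydroxylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-dependent, fragment-based featurization of alkenes for
    quantitative structure-selectivity modeling of the Sharpless asymmetric
    dihydroxylation (SAD). Identifies the reactive alkene, extracts the four
    quadrant substituents of the Sharpless/Norrby mnemonic, aligns them with a
    six-rule priority cascade, and computes a 57-feature descriptor vector
    (Sterimol, van der Waals volumes, electrostatic-potential statistics,
    conformer-averaged radial distribution functions, and a Hueckel-level
    electronic block). Maps reactant alkenes to product diols to assign
    top/bottom-face dihydroxylation independent of CIP priorities, converts
    enantiomeric excess to activation free-energy differences, fits per-class
    regression models with randomized plus Bayesian hyperparameter search,
    scores them with the Q2F3 external-validation metric, and explains
    predictions with Shapley-additive attributions. Molecule handling is backed
    by OpenBabel; a synthetic alkene generator makes the full pipeline testable
    without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    igraph,
    xgboost,
    randomForest,
    kernlab,
    e1071,
    glmnet,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.9) with RDKit (structure perception and
    conformer embedding); OpenBabel (optional charge backends)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
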