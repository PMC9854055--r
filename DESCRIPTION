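Package: FormulaLogP
Title: Structure-Agnostic Octanol-Water Partition Coefficient Modeling from
    Molecular Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting the base-10 octanol-water partition
    coefficient (LogP) of organic compounds from the molecular formula alone.
    Parses formula strings into atom counts over the ten elements C, H, N, O,
    S, P, F, Cl, Br and I; engineers the base (10-column) and extended
    (21-column) feature representations (atom counts, elemental ratios, molar
    weight, double-bond equivalents); curates mined LogP datasets (inorganic
    and duplicate filtering, isomer-spread statistics); fits and compares six
    regression models (multivariate linear, ridge, lasso, random forest,
    gradient boosting, k-nearest neighbours) under a 2-level/3-factor
    training-protocol experiment with repeated random splits and 8-fold
    cross-validated grid-search tuning; and stratifies prediction errors by
    SMILES-detected functional group.  A synthetic-data generator with a known
    atom-additive response makes every pipeline stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    xgboost,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'formula.R'
    'AllClasses.R'
    'features.R'
    'utils.R'
    'dataset.R'
    'models.R'
    'factorial.R'
    'analysis.R'
    'synthetic.R'
    'io.R'
    'FormulaLogP-package.R'
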