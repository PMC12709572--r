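Package: photoxkit
Title: Photochemical Oxidant Production by Chromophoric Organic Matter
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying photochemically produced reactive
    intermediates (hydroxyl radical, singlet oxygen, and organic triplet
    excited states) from chromophoric organic matter such as bacterial
    cellular organic matter and extracellular polymeric substances.
    Implements optical characterization (absorbance indices, fluorescence
    excitation-emission matrix indices, wavelength-integrated light
    absorption rates), non-negative trilinear PARAFAC decomposition of EEM
    cubes with scatter masking and validation diagnostics, inversion of
    chemical-probe kinetics (furfuryl alcohol, 2,4,6-trimethylphenol,
    benzene/phenol, and hexadienol isomerization) into steady-state oxidant
    concentrations and apparent quantum yields, and a statistical layer
    linking oxidant production to optical and chemical features via
    Spearman correlation, multiple linear regression with cross-validated
    forward selection, and gradient-boosted regression trees with
    permutation importance, Monte-Carlo Shapley attributions, and partial
    dependence. A synthetic-data generator with known ground truth makes
    every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xgboost,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
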