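Package: tdsolqspr
Title: Evaluation of QSPR Models for Temperature-Dependent Aqueous Solubility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating quantitative structure-property
    relationship (QSPR) models of temperature-dependent aqueous solubility
    and enthalpy of solution. Implements van't Hoff fitting and solubility
    extrapolation, the lattice-energy/sublimation-enthalpy and fusion
    relations, material-grouped pseudo-cross-validation ("remove
    temperature", CV=rt) alongside vanilla repeated stratified K-fold
    cross-validation (CV=v), seed-averaged random-forest and linear
    regression modelling with permutation importance, paired significance
    analysis of cross-validated results with multiple-testing adjustment,
    and diagnostic analyses of lattice-energy and melting-point descriptors.
    Includes a synthetic-data generator emulating the statistical structure
    of replicated temperature-dependent solubility measurements, used to
    demonstrate how standard cross-validation overestimates predictive
    performance when measurements of the same material leak across folds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
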