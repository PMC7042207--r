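Package: irfusion
Title: Two-Block Infrared Spectral Data Fusion for Geographic Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for authenticating the geographic origin of
    plant material from two co-registered vibrational-spectroscopy blocks
    (FT-NIR and ATR-FT-MIR). Implements multiplicative scatter correction and
    Savitzky-Golay second-derivative pretreatment, deterministic Kennard-Stone
    2:1 calibration/validation splitting, NIPALS PLS-DA with 7-fold
    cross-validation and a 20-iteration permutation test, random-forest
    classification with sequential out-of-bag tuning and permutation-importance
    variable selection, three data-fusion strategies (variable-level
    concatenation, PCA-feature concatenation, and fuzzy-operator decision
    fusion with majority voting), a one-vs-rest sensitivity / specificity /
    precision / efficiency evaluation suite, exploratory PCA / t-SNE /
    hierarchical clustering joined to environmental covariates, and a
    synthetic two-block spectra generator emulating the 13-region study
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mixOmics,
    jsonlite,
    knitr
Config/testthat/edition: 3
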