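Package: domfate
Title: Molecular Fate Analysis of Dissolved Organic Matter Under
    Hydroxyl Radical Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Molecular-level analysis of dissolved organic matter (DOM)
    transformation in redox-fluctuating soils probed by ultrahigh-resolution
    mass spectrometry.  Provides constrained exact-mass molecular formula
    assignment for negative-mode CHNOS(P) peak lists, Van Krevelen compound
    classification and molecular descriptors (DBE, NOSC, modified aromaticity
    index), Disappeared/Resistant/Product fate partitioning of paired
    before/after samples, paired-mass-distance reaction matching against a
    configurable transformation library, gradient-boosted fate prediction with
    exact tree-SHAP feature attribution, hydroxyl-radical probe chemistry
    arithmetic, and a synthetic-data generator that plants ground-truth fates
    and reactions for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xgboost
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
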