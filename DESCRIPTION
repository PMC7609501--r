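Package: urinebfi
Title: Discovery of Urinary Biomarkers of Food Intake from Metabolome
    Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates randomized crossover dietary interventions with
    multi-timepoint spot-urine metabolome fingerprints and recovers
    food-exposure biomarkers from them. Provides accurate-mass adduct and
    isotopologue annotation of fingerprint m/z signals with identification
    confidence levels, Latin-square menu-plan randomization and compliance
    scoring, a synthetic cohort and fingerprint generator with post-meal
    spike-and-decay kinetics and urine dilution, dilution normalization and
    binning of peak tables, random-forest classification of urine classes
    with combined importance/AUC/t-test feature selection, and cross-food
    specificity and elevation-window estimation for candidate biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
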