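Package: sdarforest
Title: Spectral Data-Activity Relationship and Decision Forest Classifiers
    for CYP Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binary classifiers of cytochrome P450 (CYP3A4/CYP2D6)
    inhibitors versus non-inhibitors from two complementary descriptor
    families: binned 13C/15N NMR chemical-shift occupancy counts analysed
    by forward stepwise linear discriminant analysis with Wilks' lambda
    partial-F entry/removal criteria (the spectral data-activity
    relationship, SDAR, approach), and numeric molecular-descriptor tables
    analysed by a decision-forest consensus of Gini-split trees built on
    mutually disjoint descriptor subsets after a Shannon-entropy
    information filter (the structure-activity relationship, SAR,
    approach). Includes repeated ten-fold cross-validation and external
    validation with sensitivity, specificity and correct-classification
    reporting, seeded synthetic data generators with planted class signal,
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
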