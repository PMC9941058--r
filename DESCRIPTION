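Package: kdmage
Title: Klemera-Doubal Biological Age, Age Acceleration and Mortality Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sex-stratified construction of Klemera-Doubal biological age
    (KDM-BA) from physical and biochemical markers via correlation-matrix
    principal components, derivation of age acceleration (KDM-AA) as the
    residual of biological age regressed on chronological age, and
    estimation of its association with all-cause mortality in a
    cardiovascular-continuum cohort using stratified Cox proportional
    hazards models on the attained-age time scale. Includes discrimination
    analysis (Harrell's C-index and two-category net reclassification
    improvement with bootstrap confidence intervals), a reproducible
    exclusion cascade with measurement harmonization and lifestyle scoring,
    and a seeded synthetic-cohort generator that emulates the latent-aging,
    grouping and survival structure the analysis assumes, with ground truth
    for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
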