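Package: abburden
Title: Anatomical Breast Burden Scoring and Schnur Scale Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the anatomical breast burden (ABB) model, a 0-6 point
    clinical scoring rubric for quantifying the burden of breast hypertrophy
    from standard in-office measurements (sternal notch-to-nipple distance,
    nipple-to-inframammary fold distance, base width, Regnault ptosis grade)
    plus patient-reported symptoms and physical findings. Provides DuBois body
    surface area computation, Schnur sliding-scale threshold lookup and
    eligibility assessment with mismatch weights, derivation of anatomical
    cutoffs from cohort data by integer group-mean scans, cohort-level
    concordance (sensitivity/specificity), Spearman correlation panels,
    stratified summary tables, and a seeded synthetic-cohort generator with
    correlated truncated-normal marginals for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils,
    MASS,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
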