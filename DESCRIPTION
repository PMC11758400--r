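Package: mcedsim
Title: Two-Step Multi-Cancer Early Detection: Cohort Simulation, Cascade
    Classification, and Screening Cost Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates case-control cohorts of protein tumor markers and
    cfDNA-derived genomic feature scores, fits a logistic probability-of-cancer
    (POC) index over a seven-marker panel, integrates five feature scores into
    a grid-searched weighted cancer risk score (CRS) calibrated so the
    98-percent-specificity cutoff sits at 2.0, applies the two-step screening
    cascade (cheap blood test first, sequencing-based test on initial
    positives), and projects case-control operating points onto a
    population-scale screening program: confusion counts, predictive values,
    likelihood ratios, number needed to screen, and per-strategy screening
    costs. Includes ROC/AUC estimation with the DeLong paired test and exact
    binomial intervals, plus an end-to-end seeded pipeline that renders the
    projection as a strategy-by-strategy report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
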