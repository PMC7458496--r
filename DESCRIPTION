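Package: swiburden
Title: Health-Economic Burden of Sternal-Wound Infections After Coronary
    Artery Bypass Graft Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A calibrated Markov cohort model of the coronary artery bypass
    graft (CABG) care pathway that quantifies the per-country clinical and
    economic burden of sternal-wound infections (SWIs). Cumulative SWI
    incidence follows a Hill dose-response curve scaled to each country's
    observed 30-day incidence; the daily-cycle pathway model tracks intensive
    care, general ward, home, SWI care, readmission and death, and converts
    excess care days into 2017 US$ burden. Includes per-country parameter
    management with midpoint merging and median/IQR imputation, probabilistic
    sensitivity analysis, a value-based-purchasing (VBP) calculator for
    risk-sharing contracts, a patient-level Monte-Carlo oracle for the cohort
    engine, and a synthetic country-table generator for fully reproducible
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
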