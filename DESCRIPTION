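Package: deathproxy
Title: Claims-Based Ascertainment of Death and Its Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for ascertaining death from monthly administrative
    healthcare claims when the enrollment (gold standard) death record is
    unavailable. Implements a family of nine claims-based death definitions
    built from discharge/disease status claims, "zombie" (post-index) claim
    screening, and Charlson comorbidity index (ICD-10) severity criteria;
    a validation engine computing sensitivity, specificity and positive
    predictive value with exact binomial confidence intervals against an
    enrollment gold standard, overall and in subgroups; a seeded synthetic
    claims-cohort generator with per-patient mechanism truth labels; and a
    Monte-Carlo simulator quantifying bias and precision loss of Cox
    hazard-ratio estimates under outcome misclassification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
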