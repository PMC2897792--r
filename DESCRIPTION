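Package: comorbidikit
Title: Claims-Based Comorbidity Measures and Their Comparative Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps ICD-9-CM inpatient claims to binary comorbidity indicators
    under the Elixhauser, Charlson/Deyo and Charlson/Romano classifications,
    with the Elixhauser DRG screen, category hierarchies, a configurable
    prior-admission rule and two ascertainment periods (index admission only,
    or index plus a one-year lookback). Builds index-hospitalization cohorts
    for acute myocardial infarction and chronic obstructive pulmonary disease,
    derives in-hospital and one-year mortality, fits baseline-plus-comorbidity
    logistic regression models, and compares measures via nested-model G2
    statistics and tie-aware c-statistics with patient-resampling bootstrap
    percentile confidence intervals. Includes a seeded synthetic-claims
    generator with ground-truth export for parameter-recovery testing, and an
    end-to-end pipeline writing machine-readable result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
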