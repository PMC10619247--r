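Package: elixadjust
Title: Elixhauser Comorbidity Risk Adjustment for Internal-Medicine Hospitalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hospital case-mix (risk) adjustment of internal-medicine
    hospitalizations with the Elixhauser comorbidity system on ICD-9-CM
    diagnosis codes. Compiles the 30 Elixhauser condition definitions into
    matchable code ranges, assigns per-hospitalization comorbidity flags with
    the diabetes and tumor hierarchies and an optional DRG screen, constructs
    four outcomes (in-hospital mortality, escalation of care, 30-day
    readmission, log length of stay), fits per-outcome logistic and linear
    models under split-sample derivation/validation, and evaluates
    discrimination (c-statistic/ROC, R-squared) and calibration
    (Hosmer-Lemeshow). Includes a seeded synthetic hospitalization generator
    that emulates the record structure of an internal-medicine electronic
    medical record extract, so the whole pipeline is testable end to end
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
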