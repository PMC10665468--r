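Package: malnut
Title: Malnutrition Risk Scores and GLIM Diagnosis from Routinely-Collected Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch computation of malnutrition screening scores and a
    routine-data operationalization of the GLIM (Global Leadership Initiative
    on Malnutrition) diagnostic criteria for orthopedic-surgery cohorts.
    Implements eight screening scores derivable from demographics,
    anthropometry and standard laboratory analytes (body weight difference
    from ideal weight, geriatric nutritional risk index, instant nutritional
    assessment, lymphocyte-albumin product, CRP/albumin ratio, a combined
    acute/chronic inflammation-protein index, the Ganzoni iron deficit, and a
    red-cell-index vitamin B deficit flag), together with age-adjusted BMI
    categories, neutrophil-lymphocyte ratio grading, cohort-relative quartile
    coding, unit-aware CSV ingestion, a seeded synthetic-cohort generator,
    and a command-line pipeline. Every score carries an explicit
    applicability contract so ragged retrospective data are scored without
    silent failures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
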