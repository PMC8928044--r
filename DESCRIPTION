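Package: sarcphen
Title: Rule-Based Computational Phenotyping and Case Validation for
    Sarcoidosis in Electronic Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and classifies sarcoidosis cases from structured
    electronic-medical-record extracts. Implements ICD-9/ICD-10 code capture
    (135 and D86.x), a clinical/radiological "index of suspicion" rule set,
    three-way case grouping (biopsy-confirmed, probable, unlikely), organ
    involvement assessment, Scadding chest-radiograph staging, pulmonary
    function test pattern interpretation, and clinical phenotype grouping.
    Provides diagnostic-validation statistics (positive predictive value and
    sensitivity with exact Clopper-Pearson intervals, chi-square and Fisher
    exact contingency tests, Welch t from summary statistics), a
    deterministic 200-patient synthetic fixture cohort with a checkable
    manifest, and a seeded stochastic cohort simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
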