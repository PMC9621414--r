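Package: cdrgrs
Title: Cup-to-Disc Ratio Genetic Risk Scores and Cognitive Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of a weighted genetic risk score
    (GRS) for vertical cup-to-disc ratio (CDR) from a candidate SNP panel,
    and covariate-adjusted association analysis of the GRS and large-CDR
    status against global cognitive function (3MSE). Implements
    imputation-quality and risk-allele concordance filtering, per-SNP
    logistic weight estimation, allele-dosage scoring, sample-selection
    quality control with an auditable report, descriptive baseline tables
    with rule-based test selection, log-scale linear models of cognitive
    scores with G-computation of adjusted mean differences, and a
    synthetic-cohort generator so the full pipeline is testable without
    controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
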