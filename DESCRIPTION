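Package: methscreen
Title: Integrative Promoter Methylation Screening and Methylation Biomarker Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of epigenetically silenced genes from paired
    methylome (Illumina 450K-style beta values) and transcriptome tables:
    differential-methylation calling at promoter CpG islands, stringent
    hyper/hypomethylation classification, integration with expression
    fold changes, and candidate ranking. Includes downstream validation
    numerics (bisulfite pyrosequencing averaging, 2^-ddCt relative
    expression, exact and approximate rank tests), patient-cohort
    biomarker evaluation (dichotomization, ROC with DeLong confidence
    intervals, logistic calibration with the Hosmer-Lemeshow test,
    clinical covariate association scans), and a seeded synthetic-data
    generator with a ground-truth manifest for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
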