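Package: sermir
Title: Serum miRNA Biomarker Discovery Pipeline with Risk-Score
    Classification and ROC Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for circulating-microRNA biomarker discovery from
    RT-qPCR threshold-cycle (CT) data in multiphase case-control studies.
    Implements composite-reference delta-CT normalization (2^-dCT relative
    expression and 2^-ddCT pooled fold change), array-based candidate
    screening with CT and fold-change criteria, low-expression (Cq)
    filtering, group comparisons, a reference-interval risk-score
    classifier with univariate logistic-regression weights, empirical ROC
    curves with DeLong or Hanley-McNeil confidence intervals, and a
    synthetic CT-level data generator for end-to-end testing of the whole
    design (pooled screening, training, validation, and an aggressive-case
    arm).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
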