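Package: cdkpredx
Title: Metagene Classification and Treatment-Interaction Analysis for
    Neoadjuvant Breast Cancer Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translational analysis of two-arm neoadjuvant breast
    cancer trials from bulk RNA-seq. Implements gene-length and
    trimmed-mean-of-M-values (TMM) normalization to log2 TPM, distance-based
    sample outlier QC, generic metagene signature scoring with cohort-quantile
    dichotomization, the three-module CDKPredX classifier (proliferation, ER
    signalling, immune activity) with external-cohort application, contingency
    and logistic-regression association statistics including
    treatment-by-biomarker interaction tests, signed-significance differential
    ranking with pre-ranked gene set enrichment, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    fgsea,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
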