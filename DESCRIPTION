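Package: mirstab
Title: Temporal-Stability Screening and Pan-Cancer Panel Selection for
    Circulating miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step discovery of circulating miRNA biomarker panels from
    small RNA-seq count matrices. Step one scores each miRNA's temporal
    stability in a healthy time course: per-timepoint log2 fold changes
    against the overall mean are summarised by a median absolute deviation
    (MAD) statistic and a median +/- k x MAD threshold window, with cosinor
    rhythmometry to confirm the absence of circadian oscillation and
    agglomerative clustering of temporal profiles. Step two screens the
    stable miRNAs across multiple cancer case/control datasets: per-dataset
    log2 fold changes falling outside a miRNA's healthy window are counted
    as outliers, and miRNAs recurrently outside their window are selected
    as a pan-cancer panel, then evaluated by ROC/AUC and a cross-validated
    panel combiner. Includes median-of-ratios count normalisation,
    expression filters, a Welch-test differential-expression stage with
    Benjamini-Hochberg correction, and a negative-binomial synthetic-data
    generator with planted temporal patterns and cancer effects for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    DESeq2,
    mclust,
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
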