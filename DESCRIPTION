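Package: tilnc
Title: Tumor-Infiltrating Immune-Related lncRNA Screening and Prognostic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens long non-coding RNAs (lncRNAs) for tumor-infiltrating
    immune-cell origin by combining top-decile expression ranking across
    immune cell types, a tissue-specificity index (TSI), and an
    immune-versus-tumor differential screen with false discovery rate
    control. Builds weighted Cox-regression risk signatures from the
    screened candidates, ships a published nine-lncRNA head and neck
    squamous cell carcinoma signature, and provides median-split risk
    stratification, Kaplan-Meier and log-rank survival comparison,
    fixed-horizon survival AUC, tumor-microenvironment summary scores,
    and a seeded synthetic-data generator with planted ground truth for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
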