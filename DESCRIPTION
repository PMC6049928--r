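Package: metabscreen
Title: NMR Bucket-Based Metabolomic Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Case-control biomarker discovery from bucketed 1D proton NMR
    spectra of biofluids and tissue extracts. Provides a synthetic cohort
    generator with known planted effects (Lorentzian lineshapes, TSP
    referencing, log-normal biological variation), bucket-window integration,
    per-bucket Welch tests with Bonferroni-corrected significance and signed
    fold changes, PCA and NIPALS PLS-DA with VIP scores and cross-validated
    R2Y/Q2, a Mahalanobis-distance F-test for scores-plot group separation,
    rank-based AUROC, volcano classification, and a combined
    -log10(p) + VIP heat-map score for longitudinal summaries across
    age, sex and sample-matrix strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    tools
Config/testthat/edition: 3
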