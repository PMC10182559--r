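Package: glycoscape
Title: Spatial Analysis of Glycogen and N-Glycan MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Glycoscape", "Developers", email = "glycoscape@example.org",
           role = c("aut", "cre"))
Description: A toolkit for spatial metabolomics of enzymatically released
    complex carbohydrates measured by MALDI mass spectrometry imaging (MSI).
    Covers exact-mass arithmetic for glucose polymer (glycogen chain-length)
    ladders and N-linked glycan compositions with sodiated adducts; curated
    peak-panel construction and tolerance-based annotation; imzML and pixel-table
    input/output; lock-mass recalibration against scan-order mass drift; panel
    peak integration and per-pixel total-ion-current normalization; unsupervised
    pixel clustering (k-nearest-neighbor graph plus Leiden community detection)
    with UMAP embedding and automated CHCA matrix-cluster removal; cluster-wise
    differential feature statistics (Wilcoxon rank-sum with Benjamini-Hochberg
    correction); glycogen chain-length profiling; on-slide standard-curve
    fitting and absolute quantitation in ng per pixel; and supervised biomarker
    scoring by PLS-DA variable importance and cross-validated multivariate ROC.
    A built-in synthetic phantom generator provides ground-truth datasets so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    xml2,
    jsonlite,
    igraph,
    FNN,
    uwot,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
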