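Package: engramassay
Title: Quantitative Analysis of Drosophila Memory-Engram Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative machinery for sparse-engram studies in
    the Drosophila mushroom body: GCaMP calcium-trace normalization and
    peak-over-threshold response calling, stimulus-specificity
    classification, T-maze performance indices with reciprocal averaging
    and forgetting-factor correction, optogenetic four-quadrant light
    preference indices, hemisphere-resolved labeled-cell-count analysis,
    and a normality-gated parametric/nonparametric statistics dispatcher.
    Includes calibrated synthetic-data generators for every assay so the
    full pipeline is testable without imaging hardware or flies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
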