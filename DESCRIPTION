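Package: lensoid
Title: Quantitative Analysis of Lens Organoid Optics and Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the light-focusing ability of lens organoid
    z-stacks (focal-ratio curves, dose-response comparisons), to run a
    self-contained negative-binomial Wald differential-expression test with
    CPM filtering and Benjamini-Hochberg FDR control, to compare
    tissue-enrichment rankings through top-fraction overlap sweeps with
    hypergeometric null expectations, and to test the concordance of regional
    differential expression with reference epithelium and fiber-cell gene
    sets via 2x2 contingency chi-squared analysis. Includes synthetic
    generators for spheroid z-stacks (geometric defocus-cone model with an
    opacity parameter) and for grouped RNA-seq count matrices with planted
    fold changes, so every analysis stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
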