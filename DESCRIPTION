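Package: sarcospot
Title: Integrative Bulk and Spatial Transcriptomic Biomarker Discovery for
    Undifferentiated Sarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-driven implementation of an
    integrative biomarker-discovery workflow for undifferentiated sarcoma:
    expression-based quality control and empirical-Bayes moderated
    differential expression on bulk tumor/normal FPKM cohorts, single-sample
    pathway scoring (Gaussian-kernel GSVA) on gene sets restricted to
    tumor-upregulated genes, an ECDF-based "quadrant spotlight" statistic
    that integrates tissue fold changes with cell-line expression
    percentiles, CosMx-style spatial single-cell quality control,
    normalization and clustering, two-pass self-referencing copy-number
    inference with tissue-wise CNV-high calling, a stepwise
    intersection-plus-membrane-evidence candidate prioritization cascade,
    and clinical immunohistochemistry (H-score) statistics. A synthetic-data
    module generates every input with known ground truth so all stages are
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
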