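Package: deconvbench
Title: Benchmarking Bulk-Tumor Deconvolution Under Protocol Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and evaluation framework for assessing cell-type
    deconvolution of bulk tumor RNA-seq under experimental-protocol
    variation. Generates virtual high-grade serous ovarian carcinoma
    cohorts as annotated single-cell references with matched
    multi-protocol bulk samples (tissue dissociation, rRNA depletion
    versus poly-A capture) and paired sample-demultiplexing posterior
    tables; builds pseudo-bulk benchmarks with RNA-fraction ground truth
    under four composition scenarios; produces downsampled and
    assignment-subset reference profiles; estimates cell-type RNA
    fractions with a built-in non-negative least squares solver behind a
    pluggable method registry; and scores methods jointly on accuracy
    (RMSE and signed differences against truth) and robustness (variance
    of estimates across bulk protocols and reference profiles), including
    demultiplexing assignment summaries, cross-modality concordance, and
    factor-level ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
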