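Package: smrlink
Title: Single-Cell Mass Response Testing and Biophysics-Transcriptome
    Association for Suspended Microchannel Resonator Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing linked single-cell biophysical and
    transcriptional measurements from suspended microchannel resonator
    (SMR) experiments. Implements the normalized Earth Mover's Distance
    "mass response" statistic with a bootstrap-t decision rule for calling
    ex vivo drug sensitivity from single-cell buoyant-mass distributions,
    a Spearman/z-score/permutation pipeline linking gene expression to
    per-cell buoyant mass and stiffness, buoyant-mass to density
    conversions, and a negative-binomial synthetic-data generator that
    emulates paired SMR/Smart-seq2 datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
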