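Package: chromdiff
Title: Differential Open Chromatin, Transcription-Factor Occupancy and
    Regulatory-Domain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing time-course chromatin accessibility
    (FAIRE-seq) and transcription-factor ChIP-seq experiments: differential
    open-chromatin calling with a replicate-permutation null, differential
    binding-site calling with a smoothed fold-change rule, position weight
    matrix scanning with exact score p-values, motif-occupancy curves
    stratified by open chromatin, strand-aware TSS annotation and
    feature-class enrichment, GREAT-style regulatory-domain gene association,
    co-occupancy and signal-correlation statistics, and classification of
    knockdown-dependent differential gene expression. Includes a synthetic
    data generator with known ground truth and a stage-based pipeline driver,
    so every analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
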