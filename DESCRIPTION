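Package: redoxtmt
Title: Two-Strain Quantitative Proteomics with TMT and iodoTMT Labeling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-strain isobaric-tag proteomics
    experiments: per-protein cysteine redox stoichiometry from
    differential iodoTMT labeling (light = reduced, heavy =
    oxidized-complement), TMT multiplex differential protein abundance
    with channel quality control, global intensity scaling, log2
    mean-centering and a SAM-style S0-moderated permutation false
    discovery rate, plus categorical enrichment statistics (Fisher's
    exact test and rank-based 1D annotation enrichment).  Includes a
    synthetic PSM-level data generator with full ground truth so that
    every stage can be validated by parameter-recovery tests without
    raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
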