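Package: swathtools
Title: Process, Quality-Control and Convert SWATH-MS/DIA Peakgroup Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the long-format peakgroup tables produced by
    OpenSWATH-style SWATH-MS/DIA pipelines: reading and dialect-based import,
    annotation with an experimental design, replicate quality control
    (analyte counts, inter-run correlation, coefficients of variation,
    summed-signal matrices), target-decoy false discovery rate estimation
    with the fraction-of-false-targets (FFT, pi0) correction at assay,
    peptide and protein level (globally and per run), m-score threshold
    calibration for a target FDR, a suite of decoy-symmetric filters, and
    disaggregation to transition level with converters to the input formats
    of MSstats, mapDIA and aLFQ.  A synthetic-data generator with
    ground-truth true/false-target labels supports validation without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
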