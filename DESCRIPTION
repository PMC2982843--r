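Package: nascentrates
Title: Nascent Transcription Rates and RNA Polymerase II Densities from
    Run-On and ChIP Array Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for converting genomic run-on (GRO) and RNA polymerase
    II ChIP-on-chip array signals into absolute nascent transcription rates
    (molecules/min) and polymerase densities (molecules/kb) for budding
    yeast genes. Implements genomic-DNA reference normalization, replicate
    validity and correlation filters, probe-length bias removal by dual
    lowess smoothing in standardized log2 space, steady-state kinetic
    calibration with an mRNA growth-dilution term, MA-style comparison of
    nascent versus indirect rates, and genome-wide transcriptional
    bookkeeping (totals, turnover, nucleosome transit, active polymerase
    census). A synthetic-data module simulates array inputs with the
    3'-labeling length bias, multiplicative noise and missing values, so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
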