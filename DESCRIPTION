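Package: fragquant
Title: Quantitative Long-Read Counting on Restriction-Fragment Length Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds equimolar restriction-fragment length standards in silico
    (IUPAC-degenerate site scanning on circular or linear genomes), counts and
    normalizes long reads per fragment from SAM/BAM alignments under
    supplementary-alignment filtering, quantifies length, ligation end-base and
    replication-gradient biases, and fits a cubic smoothing-spline spike-in
    calibration that converts raw read counts of 200 bp to 10 kb DNAs into
    corrected molar abundance estimates. Includes a truth-annotated simulator
    of biased long-read libraries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
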