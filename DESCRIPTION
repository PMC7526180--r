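Package: ksubtract
Title: In Silico Whole-Genome Subtraction for Sex-Linked Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers candidate Y (or W) chromosome sequence from
    low-coverage short reads of one heterogametic (XY) and one homogametic
    (XX) individual, without a reference genome. Overlapping read pairs are
    merged into fragments, decomposed into canonical 27-mers and counted;
    the k-mer spectrum is used to find the error valley and discard
    low-count k-mers; k-mers shared between the sexes are subtracted from
    the male set; the surviving male-specific k-mers are reassembled into
    contigs by stringent single-base unique-overlap (inchworm) extension.
    Includes in-silico PCR for marker verification, a Hardy-Weinberg
    probability model for the PCR validation panel, and a synthetic XX/XY
    genome and read simulator with ground-truth evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
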