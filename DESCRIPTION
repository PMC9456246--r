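Package: breakfish
Title: Break-Apart FISH Quantification and 4C-seq Contact Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies double-strand-break formation and broken-end mobility
    from dual-colour (break-apart) FISH confocal z-stacks: despeckling,
    iterative cylinder-fit nucleus detection, connected-component locus and
    chromosome-territory detection, mutual-nearest-neighbour allele pairing,
    signed locus-to-territory distances, quantile-based break calling and
    empirical tail-significance testing. A companion 4C-seq path performs
    in-silico restriction digestion, bait-anchored read demultiplexing,
    fragment-end contact counting, 500-kb window profiling, replicate
    normalisation, trans-contact fractions and partner-gene enrichment tests.
    Synthetic-data generators with known ground truth make every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
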