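Package: exonscout
Title: Discovery of Unannotated Exons from Cross-Species Spliced EST Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies previously unannotated internal exons (cassette exons
    and retained introns) in a target genome from spliced EST-to-genome
    alignments of related species (BLAT PSL format), applying filters for
    exon length, flanking-exon support, canonical splice sites within a
    boundary window, reading-frame preservation and novelty against
    same-species evidence. Includes an evolutionary-rate module that compares
    nonsynonymous and synonymous substitution rates (Nei-Gojobori counting
    with Jukes-Cantor correction) between a novel exon and its concatenated
    flanking exons using exact contingency tests, descriptive summaries of
    the discovered events, and a seeded synthetic-data generator that plants
    truth-tagged splicing events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
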