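Package: chiptriplet
Title: Probe-Triplet Peak Calling and Regulatory Target Analysis for
    Two-Color Promoter ChIP-chip Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls protein-bound regions from two-color promoter tiling
    microarray (ChIP-chip) data using a probe-triplet significance rule with an
    empirical permutation false discovery rate, assigns regions to the closest
    transcription start site within 10 kb, tests gene-set overlaps by the
    hypergeometric distribution, computes strand-oriented TSS-relative binding
    profiles, performs exhaustive consensus-motif discovery with mismatches over
    bound-region sequences, and matches discovered motifs against a position
    weight matrix library by column correlation.  Includes a synthetic-data
    generator that emulates a promoter array design (probes from -5.5 kb to
    +2.5 kb around each TSS) with spiked-in bound regions and planted motifs,
    providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
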