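Package: readscrub
Title: Cleaning and Quality Control of cDNA Shotgun Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Protocol-aware cleaning of single-end cDNA shotgun (454-style EST)
    reads. Identifies and trims 5' sample barcodes (MIDs) by bounded-error
    semi-global alignment, locates sequencing adapters, amplification primers
    and vector fragments with a k-mer seeded, banded Needleman-Wunsch aligner
    using separate acceptance criteria for matches in the middle and at the
    ends of a read, removes poly-A tails and poly-T heads with a
    fraction-threshold window model, and end-trims low-quality regions from
    per-base Phred scores. Reads carrying protocol artifacts (concatenated or
    misoriented primers) are classified into an erroneous-read taxonomy.
    Includes a per-step quality-control report, an over-/under-trimming
    evaluator that compares two cleaners' trim intervals against genome
    alignments in PSL format, and a synthetic-read generator with per-read
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
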