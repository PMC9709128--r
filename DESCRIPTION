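Package: bloomsig
Title: Genome-Unique K-Mer Signatures for Metagenomic Read Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents each genome of a microbial community by its genomic
    signatures: k-mers whose hash values, under a modified Bloom filter with
    genome-id entries, are touched by no other genome in the community.  The
    index is built in one or two sequential passes over the reference
    genomes, optionally thinned to signatures spaced along the genome, and
    serialized to a checksummed binary file.  Metagenomic reads are assigned
    to genomes by aggregating per-k-mer lookups with majority, first-hit or
    one-or-nothing strategies, and detected communities are scored by
    presence-level precision, recall and F1.  Includes a seeded synthetic
    community and read simulator and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    parallel,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
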