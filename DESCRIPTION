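Package: havec
Title: Exact de Bruijn Graph Storage with Quotient-Fingerprint Hashing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and queries a de Bruijn graph representation of a DNA
    read set that is exact: membership and neighbour queries never return
    false positives or false negatives. Each distinct k-mer is hashed with a
    cascade of invertible hash functions; the quotient of the hash value by
    the table size, together with the index of the hash function used, is a
    perfect fingerprint stored in a packed 5-byte (or 6-byte, with a
    saturating occurrence count) table entry alongside 4 outgoing-neighbour
    bits. k-mers for which every probe collides spill into a three-level
    auxiliary vector keyed by the last hash function's table index. Includes
    FASTA/FASTQ readers, a binary graph container, a brute-force verification
    oracle, a synthetic read simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
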