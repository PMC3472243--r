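Package: venomxtend
Title: Paired-Read Merging, Seed-Extension Assembly and Abundance
    Estimation for Venom-Gland Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and quantifying highly expressed
    transcripts from short-insert paired-end RNA-seq libraries such as
    snake venom-gland transcriptomes. Overlapping read pairs are merged
    into long composite reads by a binomial significance test on the
    observed matches in every candidate overlap; full-length transcripts
    are estimated with a greedy seed-extension assembler that hashes the
    k-mers at seed ends and concatenates non-overlapping read bases,
    with trimmed replicate seeds and a cross-replicate consensus;
    near-identical transcripts are clustered by single linkage at a
    nucleotide-divergence threshold computed over gap-free alignment
    columns; and transcript abundance is estimated from the fraction of
    reads assigned at a minimum identity. A synthetic-data generator
    reproduces the library geometry (short inserts, 3'-declining
    quality, skewed abundances, near-duplicate transcript clusters)
    with full per-read provenance for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
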