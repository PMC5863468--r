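Package: fshash
Title: Fast Incremental Spaced-Seed Hashing for DNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Rabin-Karp spaced-seed hash at every position of
    DNA sequences. Instead of re-encoding all matched symbols at each
    position, the incremental engine reuses the maximally compatible hash
    computed at a nearby previous position, for a single spaced seed or for
    several equal-span seeds hashed simultaneously. Includes a naive
    per-position reference implementation, seed-compatibility analysis
    utilities, readers for FASTA/FASTQ and seed files, a deterministic
    synthetic read simulator, and an encoded-symbol benchmark with a
    theoretical speedup predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    withr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
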