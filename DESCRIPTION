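Package: catseq
Title: Alignment-Free DNA Sequence Comparison via CAT Trilateration Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes constant-size CAT profiles for DNA sequences by scoring
    them against three fixed periodic benchmark sequences (the C-, A- and
    T-benchmarks) with exact and near-neighbor match weights and a
    previous-match bonus, then locating each sequence relative to the
    unit-separated benchmarks by trilateration (cosine theorem). Two
    sequences of any length are then compared in constant time from the six
    stored profile numbers alone, which makes the profiles usable as
    precomputed sequence metadata for fast exact-match search in large
    collections. Includes threshold similarity search over profile stores, an
    exhaustive collision-analysis harness over complete 4^n sequence spaces,
    and reference Needleman-Wunsch global alignment and Knuth-Morris-Pratt
    substring search baselines, plus FASTA ingestion, JSON-lines profile
    sidecar persistence and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
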