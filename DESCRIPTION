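Package: hmmpair
Title: Pairwise Profile HMM Alignment and Remote Homology Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds profile hidden Markov models (HMMs) from multiple sequence
    alignments and searches them against packed databases of target profile
    HMMs. Alignment uses a five-pair-state local Viterbi dynamic program with
    a compressed one-byte-per-cell backtrace, linear-memory score rows, and
    suboptimal alignments via cell exclusion; significant hits are realigned
    by Maximum Accuracy (MAC) decoding from Forward-Backward posteriors.
    Includes MSA redundancy filtering, position-specific sequence weighting
    with substitution-matrix pseudocounts, Gumbel E-value calibration, a
    two-stage column-state prefilter, chunked early termination, iterative
    profile search, deterministic synthetic-data generators, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
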