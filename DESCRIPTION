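Package: proseqid
Title: Protein Identification from Probabilistic Single-Molecule Sequencer Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates probabilistic readouts from a hypothetical single-molecule
    protein sequencer (per-position posterior probabilities over the 20 amino
    acids, under variable signal quality, reduced detectable amino-acid sets,
    fragmentation and insertion/deletion errors) and identifies the originating
    protein by building a profile hidden Markov model from each readout and
    scoring every sequence of a protein database with Forward and Viterbi
    log-odds dynamic programming. Includes a synthetic protein database
    generator, benchmarking utilities with bootstrap confidence intervals,
    experiment-grid sweep runners, and an HMMER3 ASCII profile exporter for
    cross-validation against an external search engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
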