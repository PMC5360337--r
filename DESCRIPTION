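Package: rodsearch
Title: Kinetics of Homology Recognition Between Rigid dsDNA Rods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the kinetics of homology-dependent pairing between two
    double-stranded DNA segments represented as rigid rods carrying equally
    spaced binding sites, one per helical turn. Provides the inter-rod
    interaction energy as a function of collision angle, a discrete-state
    continuous-time Markov chain over angles with irreversible unbinding,
    exact first-passage and survival calculations with a Gillespie
    stochastic-simulation cross-check, sequence-ensemble statistics of
    accidental match runs (random alphabets or genomes read from FASTA), and
    a kinetic-proofreading layer that computes specificity, delay-time
    selection, off-target dwell, total homology-search time, and the
    speed-up from correlated parallel searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
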