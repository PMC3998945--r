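Package: netquery
Title: Topology-Based Querying of Protein-Protein Interaction Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global pairwise alignment of a small query protein-protein
    interaction (PPI) network against a larger target network. The score of
    an alignment is primarily the number of conserved interactions (edge
    correctness); normalized sequence bit scores act as a strictly
    subordinate tiebreaker. Alignments are computed by an exact
    branch-and-bound solver that reports a certified upper bound and
    optimality gap, with a sequence-only assignment mode for comparison.
    Includes readers and writers for edge-list, SIF, MITAB and STRING
    network formats, an E-value-cutoff ladder pipeline, prediction of
    missing query interactions from unaligned target edges, a planted-
    alignment instance generator, and a packaged Wnt-pathway query network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
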