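Package: shattersim
Title: Simulation and Reconstruction of Progressive Chromosomal Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying complex chromosomal rearrangements and the
    proposed copy-number footprint of chromothripsis. Implements a segmented
    chromosome model with exact copy-number semantics for inversions,
    deletions and tandem duplications; breakpoint and copy-number-state
    counting under the adjacency, paired-end-sequencing and microarray
    conventions (strict and coverage-relaxed state counts); a progressive
    rearrangement simulator that realizes an observed breakpoint set one
    event at a time, with inversion-biased sampling and unconstrained (free)
    simulation; a breakpoint-graph builder that classifies components into
    derivative-chromosome paths, deleted segments and duplication cycles; and
    a native sorting-by-reversals scenario builder that reconstructs an
    explicit ordered series of inversions, deletions and tandem duplications
    explaining all observed breakpoints. A synthetic-history generator makes
    every analysis reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
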