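Package: lccontrol
Title: Structural Controllability, Control Energy, and Longest Control
    Chains in Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structural controllability of directed
    networks, with an emphasis on DTI-derived structural brain connectomes.
    Identifies minimum driver-node sets by bipartite maximum matching,
    quantifies control energy through the finite-horizon controllability
    Gramian (Van Loan block-exponential method), computes the longest control
    chain (LCC) induced by an input set, searches for minimum-cardinality
    input placements achieving a target LCC (exact and greedy distance-cover,
    plus a hub-prefix baseline), builds degree-preserving null models with
    optional rich-club destruction, performs a census of the two connected
    bidirectional 3-node motifs, and generates synthetic brain-like networks
    matching the summary statistics of 90-region AAL connectomes so that the
    whole pipeline is testable without restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
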