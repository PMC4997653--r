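Package: fblnet
Title: Feedback-Loop-Based Node Classification and Robustness of Boolean
    Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies nodes of directed biological networks by the
    feedback loops involved in their upstream and downstream paths
    (no-FBL-in-upstream and no-FBL-in-downstream nodes), simulates
    synchronous Boolean network dynamics with attractor detection, and
    empirically verifies the frozenness and robustness properties these
    classes imply. Computes the perturbation-sustainable probability, a
    max-product path score estimating how likely a single-node state
    perturbation is to persist through a feedback loop, and provides the
    downstream gene-group analyses (annotation enrichment comparisons,
    threshold sweeps, degree-preserving rewired null models) together
    with random-network and random-truth-table generators and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
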