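Package: bncoherence
Title: Attractor and Basin Coherence Analysis for Boolean Gene-Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact and Monte-Carlo stability analysis of synchronously updated
    Boolean gene-regulatory networks. Decomposes the state space into attractors
    and basins of attraction, computes state, basin, attractor and network
    coherence under single-node perturbations, and summarises ensembles through
    binned conditional-coherence curves (AUC:BC, AUC:AC) and the coherence gap.
    Classifies update rules by bias, average sensitivity, canalizing variables
    and canalizing layer structure, generates random network ensembles
    stratified by in-degree, canalizing depth or nested-canalizing layer
    structure, and provides a null-model pipeline for curated biological
    models, including source-node fixing and paired stability tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
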