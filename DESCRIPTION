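Package: complextopo
Title: Topological Profiling of Protein Complexes in Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes protein complexes embedded in binary
    protein-protein interaction networks by their graph topology.
    Computes vertex and edge k-connectivity, edge density, degree
    statistics, global and mutual clustering coefficients, triangle and
    4-cycle motif counts, and betweenness centrality on the induced
    complex graph and on two derived subgraphs (the degree-peeled
    "haircut" graph and the most highly connected subgraph).  Provides
    two null models for assessing significance: degree-preserving edge
    switching of the whole network, and size-matched random
    "pseudocomplexes" grown from triangle edges.  Includes a synthetic
    study generator (heavy-tailed background, planted bounded-neighbor
    complexes, two-hybrid-style edge noise) so the full survey pipeline
    runs without any database downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
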