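Package: rewirenet
Title: Adaptive Rewiring of Coupled Logistic-Map Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the structural evolution of binary networks of coupled
    chaotic logistic-map oscillators under synchronization-driven adaptive
    rewiring ("what fires together, wires together"), with nonuniform
    amplitude and coupling-strength parameters on a minority subset of nodes.
    Provides the rewiring simulator (with a compiled inner loop), graph
    statistics (edge density, global clustering, average path length,
    small-world index, fast-greedy modularity, degree assortativity,
    normalized rich-club profiles) for whole networks and
    minority/majority/interpartition subgraphs, random-graph baselines and
    degree-preserving null models, and model-population comparison via
    NetSimile signatures, Canberra distances, distance-based (HHG)
    independence tests, contrast and differentiation scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    e1071,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
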