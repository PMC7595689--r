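Package: nims
Title: Node-Based Informed Modularity Strategy for Anatomical Networks
Version: 0.1.0
Authors@R:
    person("Network", "Morphology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies organizational modules in small networks (anatomical
    networks in particular) with a bottom-up strategy: a local spin-glass
    module is computed around every node by seeded simulated annealing,
    duplicated and nested modules are removed, all multi-module intersections
    are tested with an exact combinatorial (chained hypergeometric) test,
    statistically supported overlaps are merged into covers, and every final
    cover is verified with a paired one-sided Wilcoxon signed-rank cohesion
    test. Includes readers and writers for GraphML and edge-list CSV, a
    planted-module fixture generator with bilateral symmetry and controlled
    overlap, and a command-line entry point.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
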