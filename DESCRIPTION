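Package: clbso
Title: Comprehensive Learning-Based Swarm Optimization for Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for two-class gene expression data
    using a hybrid binary swarm optimizer. Each swarm member combines an
    ant-style local search guided by a per-gene pheromone vector, a
    grasshopper-style global search driven by heavy-tailed (Levy-flight)
    jumps, and an adaptive comprehensive-learning phase that blends the two
    proposal streams by their recent success. The objective is
    cross-validated classifier accuracy on the selected gene subset minus a
    subset-size penalty. Includes stratified data splitting, a synthetic
    two-class expression generator with planted informative genes,
    selection-stability (Jaccard) analysis, convergence diagnostics, and an
    ablation harness for the comprehensive-learning phase.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
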