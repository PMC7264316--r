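Package: heterolp
Title: Label Propagation over Heterogeneous Drug-Disease-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based drug repositioning by semi-supervised label
    propagation over a heterogeneous network of drugs, diseases, and protein
    targets. Builds the network from three similarity and three association
    matrices, projects each bipartite layer into topological similarities,
    fuses them with the intrinsic similarities, and iteratively propagates
    known association labels to score unobserved links. Includes a
    degree-tuned bipartite-projection baseline (DT-Hybrid style), threshold
    based extraction of novel predictions, per-entity query reports, a
    synthetic block-structured network generator with hold-out machinery for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
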