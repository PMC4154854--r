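Package: ragcut
Title: Spectral Partitioning of Coarse-Grained RNA Tree Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exploring the modularity of RNA secondary structures
    through their coarse-grained tree-graph (RNA-As-Graphs) representation.
    Builds graph Laplacians, computes the algebraic connectivity and Fiedler
    vector, bisects graphs by median, sign, and largest-gap cuts of the
    Fiedler components, decomposes large graphs iteratively into minimal
    RNA modules (hairpin stems and k-way junctions) with hierarchical
    assembly plans, enumerates non-isomorphic tree topologies with
    connectivity-ordered identifiers, and converts RNA secondary structures
    (dot-bracket, CT, BPSEQ) into tree graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
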