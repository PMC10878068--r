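Package: hyperfilter
Title: Size-Dependent Filtering and Structural Analysis of Hypergraphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing higher-order (hypergraph) datasets by
    filtering hyperedges by their size. Provides the four size-dependent
    filter types (uniform, GEQ, LEQ, exclusion), filtering-set algebra,
    and the structural measures used to profile each filtering: effective
    information on the clique projection, dynamical and Pearson degree
    assortativities, betweenness centrality, and spectral community
    detection on the normalized hypergraph Laplacian with Hungarian label
    matching. Includes seeded synthetic generators with planted,
    size-stratified community structure, a sweep driver that tabulates
    metrics against the filtering parameter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
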