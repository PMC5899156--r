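Package: cliquecond
Title: Community Detection by Clique Conductance Minimization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects communities in undirected binary networks by minimizing
    clique conductance. All maximal cliques are enumerated, an induced clique
    graph is built whose edge weights sum the sizes of the maximal cliques
    shared by each vertex pair, and the clique graph is split by normalized
    spectral partitioning: a Cheeger sweep cut for two communities, a spectral
    embedding with k-means for more. Includes Girvan-Newman and
    Lancichinetti-Fortunato-Radicchi benchmark generators, normalized mutual
    information scoring, random high-dimensional geometric graphs, and
    exhaustive bipartition search for empirical verification of the expanded
    Cheeger inequality and the quadratic near-optimality bound of the sweep
    cut.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
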