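Package: limbnet
Title: Anatomical Network Analysis of Limb Musculoskeletal Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses anatomical networks, in which bones,
    cartilages and muscles are nodes and their physical contacts
    (articulations, fusions, attachments) are edges. Computes the global
    topological descriptors of such networks (density, clustering, path
    length, diameter, degree heterogeneity), tests small-world and
    hierarchical organization against ensembles of size-matched random
    graphs, detects connectivity modules with a from-scratch random-walk
    (walktrap) agglomeration selected by Newman modularity Q, and compares
    module partitions across limbs, developmental stages and pathological
    conditions via a co-classification ratio and normalized mutual
    information. Includes generators for synthetic limb-like and
    planted-partition networks so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
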