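Package: vecpath
Title: De Novo Biochemical Pathway Prediction by Shortest-Path Search in
    Compound Vector Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts biochemical (metabolic) reaction pathways between a
    start and a goal compound without requiring an initial reaction network.
    Compounds are represented as bounded-depth path-count feature vectors
    computed from their 2D structures (MDL MOL/SDF V2000); enzyme reactions
    become operator vectors, the entrywise difference between product and
    substrate vectors, gated by a substrate-inclusion condition. Pathway
    prediction is then a shortest-path search in integer-vector space,
    solved by A* with admissible heuristics: a normalized Manhattan
    distance and a Linear-Programming relaxation of the operator-count
    integer program. Includes breadth-first search as the exhaustive
    reference, enumeration of all optimal rule sequences, search
    diagnostics, and seeded synthetic fixture generators (edit networks
    and closed-circuit pathways) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
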