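Package: screp
Title: Comparing Models of Biological Systems via Labelled Simplicial Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing mathematical models of biological systems
    through their conceptual structure. Models are encoded as labelled
    abstract simplicial complexes (simplicial representations) whose
    vertices are model components and whose simplices are conceptual
    interconnections. The package detects exchange automorphisms (pairs of
    vertices in symmetric positions), reduces a representation to its final
    orbit space by iterated quotients under group actions generated by
    exchange transpositions, and decides model equivalence via
    label-constrained simplicial isomorphism between final orbit spaces.
    It also provides the partial operations on representations
    (adjacent and nonadjacent-vertex identification, vertex substitution),
    an alternative group encoding of a model as the elementary abelian
    2-group of simplex subsets under symmetric difference with its distance
    and homomorphism operations, synthetic generators with planted
    symmetries, a JSON interchange format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
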