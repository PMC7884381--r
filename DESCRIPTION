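Package: waldspace
Title: Information Geometry for Phylogenetic Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the wald space of labelled phylogenetic forests:
    Newick input and output for forests with possibly infinite edge lengths,
    split and topology combinatorics with nearest-neighbour-interchange moves,
    the two-state symmetric substitution model with exact derivatives of the
    character distribution, the Fisher information metric and its Christoffel
    symbols for both the discrete model and a Gaussian (Ornstein-Uhlenbeck)
    trait model, numerical geodesic shooting inside maximal orthants, the
    affine-invariant geometry on symmetric positive definite matrices,
    projection from the ambient matrix space onto the embedded forest space
    by Barzilai-Borwein gradient descent, and approximate boundary-crossing
    geodesics between trees of different topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
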