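Package: gordalign
Title: Gene-Order Alignment and Ancestral Genome Reconstruction on Phylogenies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs ancestral gene orders on a rooted binary species
    tree under an evolutionary model of segmental duplications, losses and
    reversals. Genomes are strings of signed gene-family symbols; the core
    engine is a dynamic-programming heuristic for the directed median
    (3-star) problem that interprets every alignment column as at most two
    evolutionary events, followed by a repair step that removes circular
    chains of duplications so that every labeling corresponds to a valid
    event history. A steinerization loop applies the 3-star solver to every
    internal node until the total tree cost stops decreasing. The package
    also provides pairwise (cherry and ancestor-descendant) aligners for
    initialization, a simulator of gene-order evolution with ground-truth
    histories, and an exhaustive exact solver for small instances used to
    benchmark the heuristic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
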