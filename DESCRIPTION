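Package: arbornet
Title: Arboreal Networks, Augmented Trees and Enhanced Quartet Tree Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combinatorial toolkit for multi-rooted phylogenetic networks
    that model horizontal gene transfer between independently rooted trees.
    Provides unrooted phylogenetic tree algebra (splits, quartets, medians,
    restriction), augmented trees (trees with marked reticulation vertices),
    the enhanced quartet tree system encoding of augmented trees together
    with its six characteristic properties and the reconstruction of the
    unique augmented tree from a valid system, arboreal networks with their
    planted form and underlying augmented tree, and the quadratic-time
    orientation algorithm that turns a binary augmented tree with a
    designated root set into an arboreal network or certifies that none
    exists.  Seeded generators for random trees, augmented trees and
    arboreal networks support property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, ape
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils-graph.R'
    'splits.R'
    'newick.R'
    'treecore.R'
    'augtree.R'
    'eqts.R'
    'properties.R'
    'reconstruct.R'
    'arboreal.R'
    'orient.R'
    'genfix.R'
    'show-methods.R'
    'arbornet-package.R'
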