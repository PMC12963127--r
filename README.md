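# arbornet

Quartet encodings of augmented phylogenetic trees, and orientation of
undirected trees into multi-rooted arboreal networks.

## The scientific problem

Horizontal gene transfer produces evolutionary histories that are not
trees: a gene moves from a donor lineage into a recipient lineage, so the
history is a forest of rooted species trees joined by transfer arcs — a
multi-rooted directed acyclic graph called an **arboreal network**. Every
vertex that receives more than one incoming arc (a **reticulation**) has
exactly one outgoing arc.

Two reconstruction questions arise:

1. **Encoding.** An unrooted tree is classically determined by the quartet
   trees (`ab|cd`) it displays. When the tree additionally carries marked
   *augmentation vertices* — placeholders for reticulations — which local
   information determines it? This package implements the **enhanced
   quartet tree system**: for each displayed quartet it records the number
   `gamma` of marked vertices on the quartet's central path and the marks
   `nu` of its two median vertices. Six properties (A1–A6) characterize
   exactly the systems that arise from augmented trees, and the augmented
   tree can be rebuilt from any system satisfying them.

2. **Orientation.** Dropping arc directions from a (planted) arboreal
   network yields an unrooted *augmented tree* whose marks sit exactly at
   the former reticulations. Given such a tree plus the set of root
   handles, the `checkOrient` algorithm recovers the unique admissible
   orientation in low-order polynomial time — or returns a certificate
   (an infeasible vertex, a pruning failure, or an endgame conflict)
   proving that none exists.

## Core model

- `UnrootedTree` — unrooted leaf-labelled tree (phylogenetic or with
  degree-2 subdivision vertices), Newick I/O via **ape**.
- `AugmentedTree` — an `UnrootedTree` plus AUG/PLAIN vertex marks;
  annotated Newick I/O (`readAugmentedNewick`, `writeAugmentedNewick`).
- `EnhancedQuartetSystem` — canonical quartet records with `gamma` and
  median marks; `inducedEQTS`, `checkProperties`, `isSupported`,
  `reconstructAugmentedTree`; TSV I/O.
- `ArborealNetwork` — multi-rooted DAG with validity checking
  (`validateArboreal`), planting (`plantNetwork`), underlying augmented
  tree (`underlyingAugmented`), arc-list I/O and Graphviz export.
- Orientation — `contractToCore`, `forcedDirection`, `checkOrient`,
  `bruteForceOrient`, `detectForbiddenConfiguration`.
- Generators — `randomBinaryTree`, `randomAugmentedTree`,
  `randomArborealNetwork`, and the property-independence fixtures
  (`independenceFixture`).

## Worked example

The five-leaf caterpillar with cherries `{1,2}` and `{4,5}`, whose
interior vertex adjacent to leaf 3 is an augmentation vertex:

```r
library(arbornet)
at <- readAugmentedNewick("((1,2),3,(4,5))AUG;")
sys <- inducedEQTS(at)
show(sys)
#> EnhancedQuartetSystem on {1, 2, 3, 4, 5}: 5 quartet record(s)
#>   1,2|3,4        gamma=0  nu=PLAIN/AUG
#>   1,2|3,5        gamma=0  nu=PLAIN/AUG
#>   1,2|4,5        gamma=1  nu=PLAIN/PLAIN
#>   1,3|4,5        gamma=0  nu=AUG/PLAIN
#>   2,3|4,5        gamma=0  nu=AUG/PLAIN
gammaOf(sys, quartet("1","2","4","5"))   # 1  (the mark lies on this path)
gammaOf(sys, quartet("1","3","4","5"))   # 0  (displayed, no mark inside)
gammaOf(sys, quartet("1","3","2","4"))   # -1 (not displayed)
checkProperties(sys)
#> PropertyReport: all six properties hold
augmentationEquivalent(reconstructAugmentedTree(sys), at)
#> TRUE
```

Orienting the underlying tree of a two-rooted network recovers it:

```r
net <- randomArborealNetwork(6, 2, seed = 11)
u <- underlyingAugmented(net)
writeAugmentedNewick(u$tree)
#> "(1,(((2,3),(5,R_2)),4),(6,R_1))AUG;"
X <- setdiff(names(augTree(u$tree)@leafMap), u$roots)
res <- checkOrient(u$tree, X, u$roots)
show(res)
#> OrientResult: SUCCESS
#> ArborealNetwork: 6 leaves, 12 vertices, 11 arcs; 2 root(s), 1 reticulation(s)
networksEqual(orientNetwork(res), net)
#> TRUE
```

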