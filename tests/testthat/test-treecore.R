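test_that("Newick parsing round-trips and rejects malformed input", {
  tr <- readNewick("((1,2),3,(4,5));")
  expect_s4_class(tr, "UnrootedTree")
  expect_identical(sort(names(tr@leafMap)), as.character(1:5))
  expect_true(treesEquivalent(readNewick(writeNewick(tr)), tr))
  ## canonical form is stable under re-orderings of the input
  expect_identical(writeNewick(readNewick("((5,4),3,(2,1));")),
                   writeNewick(tr))
  expect_error(readNewick("((1,2),3,(4,5))"), "end in ';'")
  expect_error(readNewick("(1,2,3); (4,5,6);"), "single Newick")
  expect_error(readNewick("((1,2),1,(4,5));"), "duplicate taxon")
  expect_error(readNewick("((1,2),3,((4,5)));"), "degree-two")
})

test_that("tree splits match the edge structure and invert", {
  tr <- readNewick("((1,2),3,(4,5));")
  nontriv <- treeSplits(tr, trivial = FALSE)
  expect_setequal(nontriv@splits, c("1,2|3,4,5", "1,2,3|4,5"))
  full <- treeSplits(tr)
  expect_length(full@splits, nrow(tr@edges))
  expect_true(isCompatible(full))
  expect_true(treesEquivalent(treeFromSplits(full), tr))
  ## crossing splits are incompatible and unrealizable
  bad <- splitSystem(as.character(1:5),
                     splits = c(full@splits, "1,3|2,4,5"))
  expect_false(isCompatible(bad))
  expect_error(treeFromSplits(bad), "incompatible")
})

test_that("treeFromSplits inverts treeSplits on random trees", {
  for (seed in 1:10) {
    tr <- randomBinaryTree(4 + (seed %% 9), seed)
    expect_true(treesEquivalent(treeFromSplits(treeSplits(tr)), tr))
  }
})

test_that("displayedQuartets agrees with the four-point-condition oracle", {
  expect_setequal(displayedQuartets(readNewick("((1,2),3,(4,5));")),
                  c("1,2|3,4", "1,2|3,5", "1,2|4,5", "1,3|4,5", "2,3|4,5"))
  for (seed in 11:20) {
    tr <- randomBinaryTree(5 + (seed %% 6), seed)
    expect_identical(displayedQuartets(tr), oracleQuartets(tr))
  }
})

test_that("quartet strings canonicalize", {
  expect_identical(quartet("5", "4", "2", "1"), "1,2|4,5")
  expect_identical(quartet("b", "a", "d", "c"), "a,b|c,d")
  expect_identical(quartet("c", "d", "a", "b"), "a,b|c,d")
  expect_identical(quartetTaxa("1,2|4,5"), c("1", "2", "4", "5"))
  expect_error(quartet("a", "a", "b", "c"), "distinct")
})

test_that("restriction takes the span and suppresses degree-two vertices", {
  tr <- readNewick("((1,2),3,(4,5));")
  r <- restrictTree(tr, c("1", "3", "4", "5"))
  expect_true(treesEquivalent(r$tree, readNewick("(1,3,(4,5));")))
  ## the suppressed cherry vertex of {1,2} maps to nothing; the centre maps
  ## to the centre of the restriction
  centre <- treeMedian(tr, "1", "3", "4")
  expect_identical(r$vertexMap[centre],
                   treeMedian(r$tree, "1", "3", "4"))
  expect_error(restrictTree(tr, c("1", "9")), "leaves")
})

test_that("treeMedian matches the distance-sum oracle", {
  for (seed in 21:28) {
    tr <- randomBinaryTree(6 + (seed %% 5), seed)
    taxa <- names(tr@leafMap)
    set.seed(seed)
    for (rep in 1:5) {
      xyz <- sample(taxa, 3)
      m <- treeMedian(tr, xyz[1], xyz[2], xyz[3])
      expect_identical(m, oracleMedian(tr, xyz[1], xyz[2], xyz[3]))
      ## order-independent
      expect_identical(m, treeMedian(tr, xyz[3], xyz[1], xyz[2]))
    }
  }
})

test_that("splitsFromQuartets recovers exactly the non-trivial splits", {
  for (seed in 31:40) {
    tr <- randomBinaryTree(5 + (seed %% 7), seed)
    got <- splitsFromQuartets(displayedQuartets(tr), names(tr@leafMap))
    expect_setequal(got@splits, treeSplits(tr, trivial = FALSE)@splits)
  }
  ## a non-tree quartet set yields no full split
  expect_length(splitsFromQuartets(c("a,b|c,d", "a,c|b,e"),
                                   letters[1:5])@splits, 0L)
})
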