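test_that("augmentedTree marks vertices and guards leaves", {
  tr <- readNewick("((1,2),3,(4,5));")
  centre <- treeMedian(tr, "1", "3", "4")
  at <- augmentedTree(tr, aug = centre)
  expect_identical(augVertices(at), centre)
  expect_identical(sum(augMarks(at)), 1L)
  expect_identical(augTree(at), tr)
  ## leaves can never be augmentation vertices
  expect_error(augmentedTree(tr, aug = tr@leafMap[["1"]]), "leaf")
  expect_error(augmentedTree(tr, aug = c(TRUE, FALSE)), "cover all")
})

test_that("annotated Newick IO round-trips marks", {
  at <- caterpillar5()
  expect_identical(which(augMarks(at)),
                   treeMedian(augTree(at), "1", "3", "4"))
  back <- readAugmentedNewick(writeAugmentedNewick(at))
  expect_true(augmentationEquivalent(back, at))
  ## unknown interior labels are reported and ignored
  expect_message(readAugmentedNewick("((1,2)FOO,3,(4,5));"),
                 "ignoring internal label")
  ## label placement matters: marking the cherry instead of the centre
  other <- readAugmentedNewick("((1,2),3,(4,5)AUG);")
  expect_false(augmentationEquivalent(other, at))
})

test_that("augmentationEquivalent is label-preserving isomorphism", {
  a <- readAugmentedNewick("((1,2),3,(4,5))AUG;")
  b <- readAugmentedNewick("((5,4),3,(2,1))AUG;")
  expect_true(augmentationEquivalent(a, b))
  c <- readAugmentedNewick("((1,3),2,(4,5))AUG;")
  expect_false(augmentationEquivalent(a, c))
  d <- readAugmentedNewick("((1,2),3,(4,5));")
  expect_false(augmentationEquivalent(a, d))
})

test_that("inducedEQTS computes subdivision counts and marks", {
  at <- caterpillar5()
  sys <- inducedEQTS(at)
  expect_identical(eqtsQuartets(sys),
                   c("1,2|3,4", "1,2|3,5", "1,2|4,5", "1,3|4,5", "2,3|4,5"))
  expect_identical(gammaOf(sys, "1,2|4,5"), 1L)
  expect_identical(gammaOf(sys, "1,3|4,5"), 0L)
  expect_identical(gammaOf(sys, "1,3|2,4"), -1L)
  ## the AUG centre is the near median of 1,3|4,5
  expect_identical(medianStatus(sys, "1,3|4,5", c("1", "3", "4")), "AUG")
  expect_identical(medianStatus(sys, "1,2|4,5", c("1", "2", "4")), "PLAIN")
})

test_that("inducedEQTS rejects unsuitable trees", {
  expect_error(inducedEQTS(readAugmentedNewick("(1,2,3);")), ">= 4 leaves")
  expect_error(inducedEQTS(readAugmentedNewick("(1,2,3,4);")), "star")
  subdiv <- readAugmentedNewick("((1,2),3,((4,5)));")
  expect_error(inducedEQTS(subdiv), "phylogenetic")
})

test_that("induced gamma agrees with the BFS path oracle", {
  for (seed in 41:50) {
    at <- randomAugmentedTree(5 + (seed %% 5), pAug = 0.5, seed = seed)
    sys <- inducedEQTS(at)
    for (q in eqtsQuartets(sys)) {
      expect_identical(gammaOf(sys, q), oracleGamma(at, q))
    }
  }
})
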