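test_that("random trees are deterministic per seed and leave the RNG alone", {
  set.seed(77)
  before <- .Random.seed
  t1 <- randomBinaryTree(9, seed = 123)
  expect_identical(.Random.seed, before)
  expect_true(treesEquivalent(t1, randomBinaryTree(9, seed = 123)))
  expect_false(treesEquivalent(t1, randomBinaryTree(9, seed = 124)))
  expect_identical(nrow(t1@edges), 2L * 9L - 3L)
  expect_identical(sort(names(t1@leafMap)), sort(as.character(1:9)))
  expect_identical(t1@mode, "PHYLOGENETIC")
  expect_error(randomBinaryTree(2, seed = 1))
})

test_that("random augmented trees respect pAug extremes", {
  expect_length(augVertices(randomAugmentedTree(8, 0, seed = 5)), 0L)
  full <- randomAugmentedTree(8, 1, seed = 5)
  expect_identical(sort(augVertices(full)),
                   which(lengths(.oAdj(augTree(full))) > 1L))
  a <- randomAugmentedTree(8, 0.5, seed = 9)
  expect_true(augmentationEquivalent(a, randomAugmentedTree(8, 0.5, seed = 9)))
  expect_error(randomAugmentedTree(8, 2, seed = 1))
})

test_that("random arboreal networks hit the requested root counts", {
  for (nTrees in 1:4) {
    net <- randomArborealNetwork(2 * nTrees + 3, nTrees, seed = nTrees)
    v <- validateArboreal(net)
    expect_length(v$roots, nTrees)
    expect_length(v$reticulations, nTrees - 1L)
    expect_identical(sort(names(net@leafMap)),
                     sort(as.character(seq_len(2 * nTrees + 3))))
  }
  expect_true(networksEqual(randomArborealNetwork(8, 3, seed = 2),
                            randomArborealNetwork(8, 3, seed = 2)))
  expect_error(randomArborealNetwork(5, 3, seed = 1), "nLeaves")
  ## the fixed two-root fixture used across the test suite
  net9 <- randomArborealNetwork(5, 2, seed = 0)
  expect_length(networkRoots(net9), 2L)
  expect_length(networkReticulations(net9), 1L)
})

test_that("generated networks invert through their underlying trees", {
  for (seed in 101:110) {
    net <- randomArborealNetwork(6 + (seed %% 4), 1 + (seed %% 3), seed)
    u <- underlyingAugmented(net)
    X <- setdiff(names(augTree(u$tree)@leafMap), u$roots)
    res <- checkOrient(u$tree, X, u$roots)
    expect_true(orientSuccess(res))
    expect_true(networksEqual(orientNetwork(res), net))
  }
})

test_that("independence fixtures load and are inventoried", {
  names <- independenceFixture()
  ## no shipped A5 fixture: under this formalization a system cannot violate
  ## A5 alone — a present-conclusion A5 instance is the same linear equation
  ## as an A6 instance on the same records, and the absent-conclusion
  ## configurations force A2 or A4 failures through the support conditions
  expect_setequal(names, c("A1", "A2", "A3", "A4a", "A4b", "A6a", "A6b"))
  sys <- independenceFixture("A1")
  expect_s4_class(sys, "EnhancedQuartetSystem")
  expect_error(independenceFixture("A7"), "unknown fixture")
})
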