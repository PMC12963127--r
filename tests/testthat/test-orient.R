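## The six-root worked instance: five transfer blocks hanging off a
## backbone, with handles 1^, 5^, 7^, 11^, 14^, 15^.
.sixRootTree <- function() {
  readAugmentedNewick(paste0(
    "((((1^,2),3)AUG,((5^,6),4)AUG),",
    "(((7^,8),(9,15^))AUG,((11^,10),16)AUG),((14^,13),12)AUG);"))
}
.sixRootR <- c("1^", "5^", "7^", "11^", "14^", "15^")

## forbidden-configuration instance: a central plain vertex all of whose
## branches lead to reticulations that each see exactly one taxon leaf
.forbidden3 <- function() {
  readAugmentedNewick(
    "((x1,(r1^,y1))AUG,(x2,(r2^,y2))AUG,(x3,(r3^,y3))AUG);")
}

test_that("forcedDirection implements the degree profiles", {
  expect_identical(forcedDirection("AUG", 2, 1), "SATISFIED")
  expect_identical(forcedDirection("PLAIN", 1, 2), "SATISFIED")
  expect_identical(forcedDirection("AUG", 1, 1), "IN")
  expect_identical(forcedDirection("AUG", 2, 0), "OUT")
  expect_identical(forcedDirection("PLAIN", 1, 1), "OUT")
  expect_identical(forcedDirection("PLAIN", 0, 2), "IN")
  expect_identical(forcedDirection("AUG", 0, 2), "INFEASIBLE")
  expect_identical(forcedDirection("PLAIN", 2, 0), "INFEASIBLE")
  expect_identical(forcedDirection("AUG", 1, 0), "UNDETERMINED")
  expect_identical(forcedDirection("PLAIN", 0, 0), "UNDETERMINED")
  expect_error(forcedDirection("AUG", 2, 2), "nIn")
})

test_that("contractToCore keeps handles, reticulations and their leaves", {
  t <- .sixRootTree()
  X <- setdiff(names(augTree(t)@leafMap), .sixRootR)
  cc <- contractToCore(t, X, .sixRootR)
  expect_false(cc@failed)
  core <- augTree(cc@core)
  expect_setequal(names(core@leafMap),
                  c(.sixRootR, "3", "4", "12", "16"))
  expect_setequal(
    treeSplits(core, trivial = FALSE)@splits,
    c("11^,12,14^,15^,16,4,5^,7^|1^,3",
      "11^,12,14^,15^,16,1^,3,7^|4,5^",
      "11^,12,14^,16,1^,3,4,5^|15^,7^",
      "11^,16|12,14^,15^,1^,3,4,5^,7^",
      "11^,15^,16,1^,3,4,5^,7^|12,14^",
      "11^,12,14^,15^,16,7^|1^,3,4,5^",
      "11^,15^,16,7^|12,14^,1^,3,4,5^"))
  ## every core vertex traces back to an input vertex
  expect_false(anyNA(cc@coreVertexOf))
  ## a reticulation with no handle behind it is stranded by pruning
  t2 <- readAugmentedNewick("(((1,2),(3,4))AUG,r^,(5,6));")
  cc2 <- contractToCore(t2, as.character(1:6), "r^")
  expect_true(cc2@failed)
  expect_identical(cc2@failCode, "PRUNE_STRANDED_AUG")
})

test_that("the six-root instance orients, independently of rho", {
  t <- .sixRootTree()
  X <- setdiff(names(augTree(t)@leafMap), .sixRootR)
  res <- checkOrient(t, X, .sixRootR)
  expect_true(orientSuccess(res))
  net <- orientNetwork(res)
  expect_length(networkRoots(net), 6L)
  expect_length(networkReticulations(net), 5L)
  for (rho in .sixRootR) {
    alt <- checkOrient(t, X, .sixRootR, rho = rho)
    expect_true(orientSuccess(alt))
    expect_true(networksEqual(orientNetwork(alt), net))
  }
  ## the oriented network's underlying augmented tree matches the input for
  ## the handle-to-root pairing the orientation induced (checkOrient asserts
  ## that pairing internally); here we close the loop the other way round:
  ## orienting the underlying tree of the result recovers the same network
  u <- underlyingAugmented(net)
  X2 <- setdiff(names(augTree(u$tree)@leafMap), u$roots)
  res2 <- checkOrient(u$tree, X2, u$roots)
  expect_true(orientSuccess(res2))
  expect_true(networksEqual(orientNetwork(res2), net))
})

test_that("failures carry their certificates", {
  ## reticulation with two taxon-leaf neighbours can never reach profile
  t <- readAugmentedNewick("((1,2)AUG,r^,(3,4));")
  res <- checkOrient(t, as.character(1:4), "r^")
  expect_false(orientSuccess(res))
  expect_identical(orientCode(res), "VERTEX_INFEASIBLE")
  expect_gt(length(orientWitness(res)), 0L)
  expect_null(orientNetwork(res))
  ## two handles but no reticulation to absorb the extra root
  t2 <- readAugmentedNewick("((r1^,1),2,(3,r2^));")
  res2 <- checkOrient(t2, c("1", "2", "3"), c("r1^", "r2^"))
  expect_false(orientSuccess(res2))
  expect_identical(orientCode(res2), "ENDGAME_CONFLICT")
  ## stranded reticulation, surfaced through checkOrient
  t3 <- readAugmentedNewick("(((1,2),(3,4))AUG,r^,(5,6));")
  res3 <- checkOrient(t3, as.character(1:6), "r^")
  expect_identical(orientCode(res3), "PRUNE_STRANDED_AUG")
  ## input validation
  expect_error(checkOrient(t, c(as.character(1:4), "r^"), character(0)),
               "nonempty")
  expect_error(checkOrient(t, c("1", "2", "3"), "r^"), "partition")
  expect_error(checkOrient(t, as.character(1:4), "r^", rho = "1"), "rho")
})

test_that("orientation agrees with exhaustive enumeration", {
  set.seed(404)
  for (rep in 1:20) {
    at <- randomAugmentedTree(sample(5:8, 1), pAug = 0.4,
                              seed = 500 + rep)
    taxa <- names(augTree(at)@leafMap)
    R <- sample(taxa, sample(1:2, 1))
    X <- setdiff(taxa, R)
    res <- checkOrient(at, X, R)
    all <- bruteForceOrient(at, X, R)
    expect_identical(orientSuccess(res), length(all) >= 1L)
    if (orientSuccess(res)) {
      expect_length(all, 1L)
      expect_true(networksEqual(orientNetwork(res), all[[1]]))
    }
  }
  expect_error(bruteForceOrient(underlyingAugmented(
    randomArborealNetwork(17, 1, 1))$tree, as.character(1:17), "R_1"),
    "cap|16")
})

test_that("the forbidden configuration is detected and repairable", {
  t <- .forbidden3()
  R <- c("r1^", "r2^", "r3^")
  X <- setdiff(names(augTree(t)@leafMap), R)
  w <- detectForbiddenConfiguration(t, X, R)
  expect_length(w, 1L)
  ## the witness component is the central plain vertex
  centre <- treeMedian(augTree(t), "x1", "x2", "x3")
  expect_identical(w[[1]], centre)
  expect_false(orientSuccess(checkOrient(t, X, R)))
  expect_length(bruteForceOrient(t, X, R), 0L)
  ## grafting one extra handle next to a taxon leaf removes the obstruction
  t2 <- readAugmentedNewick(
    "(((x1,r0^),(r1^,y1))AUG,(x2,(r2^,y2))AUG,(x3,(r3^,y3))AUG);")
  R2 <- c("r0^", R)
  X2 <- setdiff(names(augTree(t2)@leafMap), R2)
  expect_length(detectForbiddenConfiguration(t2, X2, R2), 0L)
  expect_true(orientSuccess(checkOrient(t2, X2, R2)))
})
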