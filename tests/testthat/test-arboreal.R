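## A hand-built two-root network: roots 6 and 7, reticulation 8 with
## parents 9 and 7, leaves 1..5.
.handNet <- function() {
  arcs <- rbind(
    c(6L, 1L), c(6L, 9L), c(9L, 2L), c(9L, 8L),
    c(7L, 8L), c(8L, 10L), c(10L, 3L), c(10L, 4L), c(7L, 5L))
  arborealNetwork(10L, arcs,
                  structure(1:5, names = as.character(1:5)))
}

test_that("construction validates the arboreal invariants", {
  net <- .handNet()
  v <- validateArboreal(net)
  expect_identical(v$roots, c(6L, 7L))
  expect_identical(v$reticulations, 8L)
  expect_identical(networkRoots(net), c(6L, 7L))
  expect_identical(networkReticulations(net), 8L)
  lm <- structure(1:2, names = c("x", "y"))
  ## wrong arc count (underlying graph not a tree)
  expect_error(arborealNetwork(4L, rbind(c(3L, 1L), c(3L, 2L)), lm),
               "arc count")
  ## root with outdegree 1 (a path) is rejected
  expect_error(arborealNetwork(3L, rbind(c(3L, 2L), c(2L, 1L)),
                               structure(1L, names = "x")),
               "total degree two|outdegree")
  ## reticulation with outdegree 2
  arcs <- rbind(c(4L, 6L), c(5L, 6L), c(6L, 1L), c(6L, 2L), c(4L, 3L),
                c(5L, 7L))
  expect_error(arborealNetwork(7L, arcs,
                               structure(c(1L, 2L, 3L, 7L),
                                         names = c("a", "b", "c", "d"))),
               "outdegree != 1")
  ## leaf map must cover exactly the outdegree-0 vertices
  expect_error(arborealNetwork(10L, .handNet()@arcs,
                               structure(1:4, names = as.character(1:4))),
               "leafMap")
})

test_that("planting adds one handle per root and unplants exactly", {
  net <- .handNet()
  p <- plantNetwork(net)
  expect_identical(names(p@handleMap), c("R_1", "R_2"))
  expect_identical(p@nVertex, net@nVertex + 2L)
  expect_identical(nrow(p@arcs), nrow(net@arcs) + 2L)
  expect_identical(unplantNetwork(p), net)
  expect_error(plantNetwork(net, handles = c("a", "a")), "collision")
  expect_error(plantNetwork(net, handles = c("1", "q")), "collision")
  expect_error(plantNetwork(net, handles = "q"), "one handle")
})

test_that("the underlying augmented tree marks exactly the reticulations", {
  net <- .handNet()
  u <- underlyingAugmented(net, handles = c("r1^", "r2^"))
  expect_identical(u$roots, c("r1^", "r2^"))
  at <- u$tree
  expect_setequal(names(augTree(at)@leafMap),
                  c(as.character(1:5), "r1^", "r2^"))
  expect_identical(augVertices(at), networkReticulations(net))
  expect_identical(augTree(at)@mode, "PHYLOGENETIC")
})

test_that("arc-list IO round-trips up to interior renaming", {
  net <- randomArborealNetwork(7, 2, seed = 4)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  writeArcs(net, path)
  expect_true(networksEqual(readArcs(path), net))
  expect_error(readArcs(textConnection("1\t2")), "#ARBOREAL")
  expect_error(readArcs(textConnection(c("#ARBOREAL v1", "a b"))),
               "malformed arc")
})

test_that("toDot renders every arc and flags reticulations", {
  net <- .handNet()
  dot <- toDot(net)
  expect_match(dot, "digraph arboreal", fixed = TRUE)
  expect_match(dot, "\"v8\" \\[style=filled")
  expect_identical(lengths(regmatches(dot, gregexpr("->", dot))),
                   nrow(net@arcs))
})

test_that("network equality ignores vertex numbering, not orientation", {
  net <- .handNet()
  ## same network with permuted interior ids
  perm <- c(1:5, 9L, 10L, 7L, 6L, 8L)
  arcs2 <- cbind(perm[net@arcs[, 1L]], perm[net@arcs[, 2L]])
  net2 <- arborealNetwork(10L, arcs2, structure(1:5, names = as.character(1:5)))
  expect_true(networksEqual(net, net2))
  expect_false(networksEqual(net, randomArborealNetwork(5, 2, seed = 0)))
  ## same underlying tree, different reticulation: compare two orientations
  u <- underlyingAugmented(net)
  X <- setdiff(names(augTree(u$tree)@leafMap), u$roots)
  all9 <- bruteForceOrient(u$tree, X, u$roots)
  expect_true(any(vapply(all9, networksEqual, logical(1), y = net)))
})
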