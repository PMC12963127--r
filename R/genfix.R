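## Reproducible random generators for trees and networks, and the shipped
## counterexample fixtures for the six characteristic properties.

## Evaluate expr under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Grow an unrooted binary tree on taxa "1".."n" by stepwise leaf addition,
## using the current RNG stream.  Leaves get vertex ids 1..n.
.growBinaryTree <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 3L)
  nv <- n + 1L
  edges <- rbind(c(nv, 1L), c(nv, 2L), c(nv, 3L))
  for (k in seq_len(n)[-(1:3)]) {
    i <- sample.int(nrow(edges), 1L)
    nv <- nv + 1L
    uv <- edges[i, ]
    edges <- rbind(edges[-i, , drop = FALSE],
                   c(uv[1L], nv), c(nv, uv[2L]), c(nv, k))
  }
  lm <- structure(seq_len(n), names = as.character(seq_len(n)))
  .newUnrootedTree(nv, edges, lm, mode = TREE_PHYLOGENETIC)
}

#' Random binary trees and augmented trees
#'
#' \code{randomBinaryTree} grows an unrooted binary tree on taxa
#' \code{"1"}..\code{"n"} by stepwise addition: starting from the star on
#' three leaves, each further leaf is attached to a uniformly chosen edge.
#' \code{randomAugmentedTree} additionally marks each interior vertex AUG
#' independently with probability \code{pAug}.  Both restore the caller's
#' RNG state.
#'
#' @param n number of leaves (>= 3).
#' @param seed integer seed; equal seeds give equal trees.
#' @return \code{randomBinaryTree}: an \linkS4class{UnrootedTree} with
#'   \code{2n - 3} edges; \code{randomAugmentedTree}: an
#'   \linkS4class{AugmentedTree}.
#' @examples
#' randomBinaryTree(6, seed = 1)
#' randomAugmentedTree(6, pAug = 0.5, seed = 1)
#' @export
randomBinaryTree <- function(n, seed) {
  .withSeed(seed, .growBinaryTree(n))
}

#' @rdname randomBinaryTree
#' @param pAug probability in [0, 1] that an interior vertex is marked AUG.
#' @export
randomAugmentedTree <- function(n, pAug, seed) {
  stopifnot(is.numeric(pAug), length(pAug) == 1L, pAug >= 0, pAug <= 1)
  .withSeed(seed, {
    tr <- .growBinaryTree(n)
    interior <- which(.degrees(tr) > 1L)
    aug <- interior[stats::runif(length(interior)) < pAug]
    augmentedTree(tr, aug = aug)
  })
}

## Grow a rooted binary tree over the given (global) leaf vertex ids; the
## root has outdegree 2 and every other interior vertex indegree 1 and
## outdegree 2.  Returns the arc matrix and the next free vertex id.
.growRootedComponent <- function(leafIds, nextId) {
  stopifnot(length(leafIds) >= 2L)
  root <- nextId
  nextId <- nextId + 1L
  arcs <- rbind(c(root, leafIds[1L]), c(root, leafIds[2L]))
  for (k in seq_along(leafIds)[-(1:2)]) {
    i <- sample.int(nrow(arcs), 1L)
    w <- nextId
    nextId <- nextId + 1L
    uv <- arcs[i, ]
    arcs <- rbind(arcs[-i, , drop = FALSE],
                  c(uv[1L], w), c(w, uv[2L]), c(w, leafIds[k]))
  }
  list(arcs = arcs, nextId = nextId, root = root)
}

.growArborealNetwork <- function(nLeaves, nTrees) {
  ## partition the taxa into nTrees groups of size >= 2
  sizes <- rep(2L, nTrees)
  extra <- nLeaves - 2L * nTrees
  if (extra > 0L) {
    more <- tabulate(sample.int(nTrees, extra, replace = TRUE), nbins = nTrees)
    sizes <- sizes + more
  }
  groups <- split(sample.int(nLeaves), rep(seq_len(nTrees), sizes))
  comp <- integer(nLeaves)
  for (g in seq_len(nTrees)) comp[groups[[g]]] <- g
  nextId <- nLeaves + 1L
  arcs <- matrix(integer(0), 0L, 2L)
  for (g in seq_len(nTrees)) {
    grown <- .growRootedComponent(groups[[g]], nextId)
    comp[seq.int(nextId, grown$nextId - 1L)] <- g
    nextId <- grown$nextId
    arcs <- rbind(arcs, grown$arcs)
  }
  ## connect the components into a tree of trees with one transfer arc per
  ## new component: the tail subdivides an arc of the donor component, the
  ## head one of the recipient, making the head a reticulation
  for (j in seq_len(nTrees)[-1L]) {
    pair <- c(j, sample.int(j - 1L, 1L))
    if (stats::runif(1L) < 0.5) pair <- rev(pair)
    donor <- pair[1L]
    recipient <- pair[2L]
    sub <- function(cmp) {
      rows <- which(comp[arcs[, 1L]] == cmp & comp[arcs[, 2L]] == cmp)
      i <- rows[sample.int(length(rows), 1L)]
      uv <- arcs[i, ]
      v <- nextId
      comp[v] <<- cmp
      nextId <<- nextId + 1L
      arcs <<- rbind(arcs[-i, , drop = FALSE], c(uv[1L], v), c(v, uv[2L]))
      v
    }
    tail <- sub(donor)
    head <- sub(recipient)
    arcs <- rbind(arcs, c(tail, head))
  }
  lm <- structure(seq_len(nLeaves), names = as.character(seq_len(nLeaves)))
  arborealNetwork(nextId - 1L, arcs, lm)
}

#' Random arboreal network
#'
#' Draws an arboreal network: the taxa are partitioned into \code{nTrees}
#' groups of at least two, each group grows a rooted binary tree by
#' stepwise leaf addition, and the components are joined into a tree of
#' trees by \code{nTrees - 1} transfer arcs whose heads are reticulation
#' vertices (the tail subdivides an arc of one component, the head an arc
#' of the other).  The result has \code{nTrees} roots and
#' \code{nTrees - 1} reticulations.  Restores the caller's RNG state.
#'
#' @param nLeaves number of taxa; at least \code{2 * nTrees}, so that each
#'   root retains outdegree 2.
#' @param nTrees number of roots (>= 1).
#' @param seed integer seed; equal seeds give equal networks.
#' @return an \linkS4class{ArborealNetwork} on taxa
#'   \code{"1"}..\code{"nLeaves"}.
#' @examples
#' net <- randomArborealNetwork(5, 2, seed = 0)
#' networkRoots(net)
#' @export
randomArborealNetwork <- function(nLeaves, nTrees, seed) {
  nLeaves <- as.integer(nLeaves)
  nTrees <- as.integer(nTrees)
  stopifnot(nTrees >= 1L, nLeaves >= 2L * nTrees)
  seed <- as.integer(seed)
  for (attempt in seq_len(5L)) {
    s <- if (attempt == 1L) seed else {
      (abs(seed) %% 65536L) * 31337L + attempt
    }
    net <- .withSeed(s, tryCatch(.growArborealNetwork(nLeaves, nTrees),
                                 error = function(e) e))
    if (!inherits(net, "error")) return(net)
    message("draw ", attempt, " rejected (", conditionMessage(net),
            "); retrying with derived seed")
  }
  stop("failed to draw a valid arboreal network after 5 attempts")
}

#' Counterexample fixtures for the characteristic properties
#'
#' Ships seven quartet systems, each violating exactly one of the
#' characteristic properties while satisfying all the others; they witness
#' that none of those checks is implied by the remaining ones.  Names:
#' \code{"A1"}, \code{"A2"}, \code{"A3"}, \code{"A4a"}, \code{"A4b"},
#' \code{"A6a"}, \code{"A6b"} (two structurally different witnesses each for
#' the fourth and sixth property).  No fixture fails A5 alone: a system with
#' the conclusion record of an A5 instance present satisfies the identical
#' linear equation as an A6 instance on the same records, and the
#' absent-conclusion configurations force A2 or A4 failures through the
#' support conditions, so A5-only violations are unattainable.
#'
#' @param name fixture name, or missing to list the available names.
#' @return an \linkS4class{EnhancedQuartetSystem}, or a character vector of
#'   names when \code{name} is missing.
#' @examples
#' independenceFixture()
#' reportViolations(checkProperties(independenceFixture("A1")), "A1")
#' @export
independenceFixture <- function(name) {
  dir <- system.file("extdata", "fixtures", package = "arbornet")
  avail <- sort(sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$")))
  if (missing(name)) return(avail)
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% avail) {
    stop("unknown fixture '", name, "'; available: ",
         paste(avail, collapse = ", "))
  }
  readEQTS(file.path(dir, paste0(name, ".tsv")))
}
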