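## Quartet/median/restriction operations on unrooted trees.

#' Quartet trees displayed by a phylogenetic tree
#'
#' A quartet tree ab|cd is displayed by T when the restriction of T to
#' \{a,b,c,d\} equals it; equivalently when some non-trivial split of T
#' separates \{a,b\} from \{c,d\}.  Computed from the non-trivial splits.
#'
#' @param tree a phylogenetic \linkS4class{UnrootedTree} with >= 4 leaves.
#' @return character vector of canonical quartet strings (sorted).
#' @examples
#' displayedQuartets(readNewick("((1,2),3,(4,5));"))
#' @export
displayedQuartets <- function(tree) {
  stopifnot(is(tree, "UnrootedTree"))
  if (length(tree@leafMap) < 4L) stop("tree must have >= 4 leaves")
  sys <- treeSplits(tree, trivial = FALSE)
  out <- character(0)
  for (s in sys@splits) {
    p <- .splitParts(s)
    out <- c(out, .splitQuartets(p$a, p$b))
  }
  .sortTaxa(unique(out))
}

#' Restriction of a tree to a taxon subset
#'
#' Takes the span (minimal connected subgraph joining the chosen leaves) and
#' suppresses its degree-two vertices.  The returned vertex map traces span
#' vertices into the restriction so that medians can be followed across
#' restrictions.
#'
#' @param tree an \linkS4class{UnrootedTree}.
#' @param taxa character vector, a subset of the leaf taxa with >= 2
#'   elements.
#' @return list with elements \code{tree} (the restriction, an
#'   \linkS4class{UnrootedTree} on \code{taxa}) and \code{vertexMap}
#'   (integer vector over the original vertex ids: the image vertex in the
#'   restriction, or NA for vertices outside the span or suppressed).
#' @export
restrictTree <- function(tree, taxa) {
  stopifnot(is(tree, "UnrootedTree"))
  if (!all(taxa %in% names(tree@leafMap))) stop("taxa must be leaves of the tree")
  taxa <- .sortTaxa(unique(taxa))
  if (length(taxa) < 2L) stop("need >= 2 taxa")
  tips <- .leafVertex(tree, taxa)
  ## span = union of paths from each tip to the first tip
  inSpan <- logical(tree@nVertex)
  parent <- .parentsFrom(tree, tips[1L])
  for (t in tips) {
    v <- t
    while (v != 0L && !inSpan[v]) { inSpan[v] <- TRUE; v <- parent[v] }
  }
  spanV <- which(inSpan)
  spanEdges <- tree@edges[inSpan[tree@edges[, 1L]] & inSpan[tree@edges[, 2L]],
                          , drop = FALSE]
  cp <- .compactVertices(tree@nVertex, spanEdges, spanV)
  sup <- .suppressDegreeTwo(cp$n, cp$edges, protect = cp$map[tips])
  cp2 <- .compactVertices(cp$n, sup$edges, sup$keep)
  lm <- structure(cp2$map[cp$map[tips]], names = taxa)
  rt <- .newUnrootedTree(cp2$n, cp2$edges, lm)
  validObject(rt)
  vertexMap <- rep(NA_integer_, tree@nVertex)
  kept <- sup$keep                     # ids in compacted span space
  vertexMap[spanV] <- {
    m <- cp2$map[cp$map[spanV]]
    m[m == 0L] <- NA_integer_
    m
  }
  list(tree = rt, vertexMap = vertexMap)
}

#' Median vertex of three leaves
#'
#' The unique vertex lying simultaneously on the three pairwise paths
#' between \code{x}, \code{y} and \code{z}; order-independent.
#'
#' @param tree an \linkS4class{UnrootedTree}.
#' @param x,y,z distinct taxon labels.
#' @return integer(1), a vertex id of \code{tree}.
#' @export
treeMedian <- function(tree, x, y, z) {
  stopifnot(is(tree, "UnrootedTree"))
  tx <- c(x, y, z)
  if (length(unique(tx)) != 3L) stop("x, y, z must be distinct")
  v <- .leafVertex(tree, tx)
  .medianVertex(tree, v[1L], v[2L], v[3L])
}

## The two median vertices of a displayed quartet key in `tree`, in the
## canonical order (pair-1-side first).  Quartet must be displayed.
.quartetMedianVertices <- function(tree, key) {
  tx <- .quartetTaxa(key)
  m1 <- treeMedian(tree, tx[1L], tx[2L], tx[3L])
  m2 <- treeMedian(tree, tx[3L], tx[4L], tx[1L])
  c(m1, m2)
}
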