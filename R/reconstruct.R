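## Reconstruction of the unique augmented tree realizing a quartet system.

.failReconstruct <- function(stage, msg) {
  stop(structure(class = c("notRealizable", "error", "condition"),
                 list(message = paste0("[", stage, "] ", msg),
                      call = NULL, stage = stage)))
}

## Any leaf of `tree` inside the component of `to` after deleting `from`.
.leafToward <- function(tree, from, to, adj = NULL, deg = NULL) {
  if (is.null(adj)) adj <- .adjList(tree@nVertex, tree@edges)
  if (is.null(deg)) deg <- lengths(adj)
  prev <- from; cur <- to
  while (deg[cur] != 1L) {
    nxt <- setdiff(adj[[cur]], prev)[1L]
    prev <- cur; cur <- nxt
  }
  cur
}

#' Reconstruct the augmented tree realizing a quartet system
#'
#' Inverts \code{\link{inducedEQTS}}: given an enhanced quartet tree system,
#' returns the unique augmented phylogenetic tree (up to
#' augmentation-equivalence) that induces it, or signals a classed error of
#' class \code{"notRealizable"} when no augmented tree does.  The error
#' condition carries a \code{stage} field naming the step that failed:
#' \code{"splits"} (the support does not yield a compatible split system),
#' \code{"quartets"} (the tree built from the splits displays a different
#' support), or \code{"verification"} (no marking of the tree's interior
#' vertices induces the given subdivision counts and median marks).  A
#' system passes \code{\link{checkProperties}} if and only if
#' reconstruction succeeds.
#'
#' @param sys an \linkS4class{EnhancedQuartetSystem}.
#' @return an \linkS4class{AugmentedTree} on the system's taxa.
#' @examples
#' at <- readAugmentedNewick("((1,2),3,(4,5)AUG);")
#' augmentationEquivalent(reconstructAugmentedTree(inducedEQTS(at)), at)
#' @export
reconstructAugmentedTree <- function(sys) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  ground <- sys@ground

  ## 1: candidate splits from the support, plus the trivial ones
  nontriv <- splitsFromQuartets(sys@quartets, ground)
  triv <- vapply(ground, function(x) .splitKey(x, setdiff(ground, x)),
                 character(1))
  full <- splitSystem(ground, splits = c(nontriv@splits, unname(triv)))
  tr0 <- tryCatch(treeFromSplits(full), error = function(e)
    .failReconstruct("splits", conditionMessage(e)))

  ## 2: the tree must display exactly the support
  disp <- if (length(treeSplits(tr0, trivial = FALSE)@splits)) {
    displayedQuartets(tr0)
  } else character(0)
  if (!identical(disp, sys@quartets)) {
    .failReconstruct("quartets",
                     "support is not the displayed quartet set of a tree")
  }

  ## 3: mark interior vertices from the median marks of the records
  marks <- rep(NA, tr0@nVertex)
  deg0 <- .degrees(tr0)
  marks[deg0 == 1L] <- FALSE
  for (i in seq_along(sys@quartets)) {
    key <- sys@quartets[i]
    m <- .quartetMedianVertices(tr0, key)
    if (is.na(marks[m[1L]])) marks[m[1L]] <- sys@nuNear[i] == MARK_AUG
    if (is.na(marks[m[2L]])) marks[m[2L]] <- sys@nuFar[i] == MARK_AUG
  }
  ## every interior vertex is the median of some displayed quartet
  stopifnot(!anyNA(marks))
  at <- augmentedTree(tr0, aug = marks)

  ## 4: full verification against the input, record by record
  if (!eqtsEqual(inducedEQTS(at), sys)) {
    .failReconstruct("verification",
                     "marked tree does not induce the given system")
  }
  at
}
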