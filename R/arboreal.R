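## Arboreal networks: multi-rooted DAGs whose planted, undirected form is a
## phylogenetic tree.  Planting, the underlying augmented tree, IO, and
## network equality.

.arcDegrees <- function(nVertex, arcs) {
  list(indeg = tabulate(arcs[, 2L], nbins = nVertex),
       outdeg = tabulate(arcs[, 1L], nbins = nVertex))
}

## NULL when valid, otherwise a message.  Acyclicity needs no separate
## check: the underlying graph is a tree, and any directed cycle would
## induce an undirected one.
.arborealProblems <- function(object) {
  n <- object@nVertex
  a <- object@arcs
  if (n < 2L) return("network must have at least two vertices")
  if (!is.matrix(a) || ncol(a) != 2L) return("arcs must be a 2-column matrix")
  if (nrow(a) != n - 1L) return("arc count must be nVertex - 1")
  if (any(a < 1L) || any(a > n)) return("arc endpoint out of range")
  if (any(a[, 1L] == a[, 2L])) return("self-loop arc")
  if (!.allConnected(n, a)) return("underlying graph is not a tree")
  d <- .arcDegrees(n, a)
  ret <- which(d$indeg >= 2L)
  if (any(d$outdeg[ret] != 1L)) {
    return("reticulation (indegree >= 2) with outdegree != 1")
  }
  roots <- which(d$indeg == 0L)
  if (any(d$outdeg[roots] < 2L)) return("root with outdegree < 2")
  nonroot <- which(d$indeg > 0L)
  if (any((d$indeg + d$outdeg)[nonroot] == 2L)) {
    return("non-root vertex of total degree two")
  }
  leaves <- which(d$outdeg == 0L)
  lm <- object@leafMap
  taxa <- names(lm)
  if (length(lm) != length(leaves) || !setequal(lm, leaves)) {
    return("leafMap must map taxa onto the outdegree-0 vertices, bijectively")
  }
  if (anyDuplicated(taxa) || anyDuplicated(lm)) {
    return("duplicate taxon label or leaf vertex")
  }
  if (!all(.validTaxon(taxa))) return("invalid taxon label")
  NULL
}

#' Construct an arboreal network
#'
#' @param nVertex integer(1), number of vertices (opaque ids 1..nVertex).
#' @param arcs integer matrix with columns (tail, head), one row per arc.
#' @param leafMap named integer vector mapping taxa to the outdegree-0
#'   vertices.
#' @return a validated \linkS4class{ArborealNetwork}.
#' @export
arborealNetwork <- function(nVertex, arcs, leafMap) {
  storage.mode(arcs) <- "integer"
  lm <- as.integer(leafMap)
  names(lm) <- names(leafMap)
  lm <- lm[.sortTaxa(names(lm))]
  obj <- new("ArborealNetwork", nVertex = as.integer(nVertex), arcs = arcs,
             leafMap = lm)
  validObject(obj)
  obj
}

#' Validate an arboreal network and report its roots and reticulations
#'
#' @param x an \linkS4class{ArborealNetwork} (or candidate; errors with the
#'   first violated invariant otherwise).
#' @return list with integer vertex-id vectors \code{roots} (indegree 0)
#'   and \code{reticulations} (indegree >= 2).
#' @export
validateArboreal <- function(x) {
  stopifnot(is(x, "ArborealNetwork"))
  msg <- .arborealProblems(x)
  if (!is.null(msg)) stop(msg)
  d <- .arcDegrees(x@nVertex, x@arcs)
  list(roots = which(d$indeg == 0L), reticulations = which(d$indeg >= 2L))
}

#' Network roots and reticulation vertices
#'
#' @param x an \linkS4class{ArborealNetwork}.
#' @return integer vector of vertex ids.
#' @export
networkRoots <- function(x) {
  stopifnot(is(x, "ArborealNetwork"))
  which(.arcDegrees(x@nVertex, x@arcs)$indeg == 0L)
}

#' @rdname networkRoots
#' @export
networkReticulations <- function(x) {
  stopifnot(is(x, "ArborealNetwork"))
  which(.arcDegrees(x@nVertex, x@arcs)$indeg >= 2L)
}

## vertex display names: taxa for leaves, v<id> for interior vertices
.vertexNames <- function(x) {
  nm <- paste0("v", seq_len(x@nVertex))
  nm[x@leafMap] <- names(x@leafMap)
  nm
}

#' Read and write arboreal networks as arc lists
#'
#' Plain-text format: a line \code{#ARBOREAL v1} followed by one
#' \code{tail<TAB>head} line per arc.  Vertex names are identifiers; the
#' names of outdegree-0 vertices are the taxa.  Interior names are
#' preserved on read but regenerated (\code{v<id>}) on write, so round
#' trips are exact up to interior renaming.
#'
#' @param path file path (or connection for \code{readArcs}).
#' @return \code{readArcs}: an \linkS4class{ArborealNetwork};
#'   \code{writeArcs}: invisibly, \code{path}.
#' @export
readArcs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], "#ARBOREAL")) {
    stop("not an arc-list file (missing '#ARBOREAL' header)")
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no arcs")
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed arc line (need tail\\thead)")
  m <- do.call(rbind, parts)
  nm <- unique(as.vector(t(m)))
  id <- structure(seq_along(nm), names = nm)
  arcs <- cbind(id[m[, 1L]], id[m[, 2L]])
  outdeg <- tabulate(arcs[, 1L], nbins = length(nm))
  leaves <- which(outdeg == 0L)
  arborealNetwork(length(nm), arcs, structure(leaves, names = nm[leaves]))
}

#' @rdname readArcs
#' @param x an \linkS4class{ArborealNetwork}.
#' @export
writeArcs <- function(x, path) {
  stopifnot(is(x, "ArborealNetwork"))
  nm <- .vertexNames(x)
  writeLines(c("#ARBOREAL v1",
               paste(nm[x@arcs[, 1L]], nm[x@arcs[, 2L]], sep = "\t")), path)
  invisible(path)
}

#' DOT rendering of an arboreal network
#'
#' @param x an \linkS4class{ArborealNetwork}.
#' @return character(1), a Graphviz \code{digraph} with one edge per arc;
#'   leaves are boxed, reticulations filled.
#' @export
toDot <- function(x) {
  stopifnot(is(x, "ArborealNetwork"))
  nm <- .vertexNames(x)
  ret <- networkReticulations(x)
  decl <- c(
    paste0("  \"", nm[x@leafMap], "\" [shape=box];"),
    if (length(ret)) paste0("  \"", nm[ret],
                            "\" [style=filled, fillcolor=gray];")
  )
  edges <- paste0("  \"", nm[x@arcs[, 1L]], "\" -> \"", nm[x@arcs[, 2L]],
                  "\";")
  paste(c("digraph arboreal {", decl, edges, "}"), collapse = "\n")
}

#' Plant and unplant an arboreal network
#'
#' Planting adds, for each root r, a new handle vertex r-hat with the arc
#' (r-hat, r); the planted underlying undirected graph is then a
#' phylogenetic tree on X together with the handle names.
#'
#' @param x an \linkS4class{ArborealNetwork}.
#' @param handles character vector of handle names, one per root in
#'   ascending root-vertex-id order; default \code{R_1, R_2, ...}.
#' @return \code{plantNetwork}: a \linkS4class{PlantedNetwork};
#'   \code{unplantNetwork}: the original \linkS4class{ArborealNetwork}.
#' @export
plantNetwork <- function(x, handles = NULL) {
  stopifnot(is(x, "ArborealNetwork"))
  roots <- networkRoots(x)
  k <- length(roots)
  if (is.null(handles)) handles <- paste0("R_", seq_len(k))
  if (length(handles) != k) stop("need one handle name per root")
  if (anyDuplicated(handles) || any(handles %in% names(x@leafMap))) {
    stop("handle name collision")
  }
  if (!all(.validTaxon(handles))) stop("invalid handle name")
  n <- x@nVertex
  hv <- n + seq_len(k)
  new("PlantedNetwork",
      network = x,
      nVertex = n + k,
      arcs = rbind(x@arcs, cbind(hv, roots)),
      leafMap = x@leafMap,
      handleMap = structure(hv, names = handles))
}

#' @rdname plantNetwork
#' @param p a \linkS4class{PlantedNetwork}.
#' @export
unplantNetwork <- function(p) {
  stopifnot(is(p, "PlantedNetwork"))
  p@network
}

#' Underlying augmented tree of an arboreal network
#'
#' Plants the network, drops arc directions, and marks exactly the
#' reticulation vertices AUG.  The handle names become extra leaf taxa; by
#' construction the result is a phylogenetic augmented tree and no AUG
#' vertex is adjacent to more than one leaf (asserted).
#'
#' @param x an \linkS4class{ArborealNetwork}.
#' @param handles handle names passed to \code{\link{plantNetwork}}.
#' @return list with elements \code{tree} (an \linkS4class{AugmentedTree}
#'   on X union the handle names) and \code{roots} (the handle names).
#' @export
underlyingAugmented <- function(x, handles = NULL) {
  stopifnot(is(x, "ArborealNetwork"))
  p <- plantNetwork(x, handles = handles)
  lm <- c(p@leafMap, p@handleMap)
  tr <- .newUnrootedTree(p@nVertex, p@arcs, lm)
  validObject(tr)
  aug <- logical(p@nVertex)
  aug[networkReticulations(x)] <- TRUE
  at <- augmentedTree(tr, aug = aug)
  ## a reticulation can have at most one leaf child; asserted, not assumed
  adj <- .adjList(tr@nVertex, tr@edges)
  deg <- lengths(adj)
  for (v in which(aug)) {
    stopifnot(sum(deg[adj[[v]]] == 1L) <= 1L)
  }
  list(tree = at, roots = names(p@handleMap))
}

## Canonical directed serialization given a handle naming: the planted
## tree's canonical Newick with per-edge tags recording arc directions
## ("^" = arc points rootward in the serialization, "=" = leafward).
.canonicalNetString <- function(x, handles) {
  p <- plantNetwork(x, handles = handles)
  lm <- c(p@leafMap, p@handleMap)
  tr <- .newUnrootedTree(p@nVertex, p@arcs, lm)
  down <- new.env(hash = TRUE)
  for (i in seq_len(nrow(p@arcs))) {
    assign(paste(p@arcs[i, 1L], p@arcs[i, 2L]), TRUE, envir = down)
  }
  tag <- function(parent, child) {
    if (!is.null(down[[paste(parent, child)]])) "=" else "^"
  }
  .canonicalString(tr, arcTag = tag)
}

#' Equality of arboreal networks
#'
#' True when a taxon-preserving isomorphism of directed graphs maps one
#' network onto the other; interior vertex ids are immaterial.  Computed by
#' comparing canonical directed serializations over all matchings of the
#' two root sets.
#'
#' @param x,y \linkS4class{ArborealNetwork} objects.
#' @return logical(1); networks on different taxon sets compare FALSE.
#' @export
networksEqual <- function(x, y) {
  stopifnot(is(x, "ArborealNetwork"), is(y, "ArborealNetwork"))
  if (!setequal(names(x@leafMap), names(y@leafMap))) return(FALSE)
  kx <- length(networkRoots(x))
  ky <- length(networkRoots(y))
  if (kx != ky) return(FALSE)
  base <- paste0("H", seq_len(kx))
  while (any(base %in% names(x@leafMap))) base <- paste0(base, "h")
  sx <- .canonicalNetString(x, base)
  perms <- .permutations(kx)
  for (i in seq_len(nrow(perms))) {
    if (identical(sx, .canonicalNetString(y, base[perms[i, ]]))) return(TRUE)
  }
  FALSE
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}
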