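## Internal graph helpers on the integer edge-matrix representation.
## All are O(n) or O(n log n); trees here are small (tens to hundreds of
## vertices), so clarity wins over asymptotics.

.sortTaxa <- function(x) sort(x, method = "radix")

.adjList <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

.degrees <- function(tree) tabulate(as.integer(tree@edges), nbins = tree@nVertex)

.allConnected <- function(n, edges) {
  if (n == 1L) return(TRUE)
  adj <- .adjList(n, edges)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

## Parent array of the tree rooted at `root` (parent[root] = 0).
.parentsFrom <- function(tree, root, adj = NULL) {
  n <- tree@nVertex
  if (is.null(adj)) adj <- .adjList(n, tree@edges)
  parent <- integer(n)
  parent[root] <- 0L
  seen <- logical(n)
  seen[root] <- TRUE
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  parent
}

## Vertex path from u to v (inclusive).
.treePath <- function(tree, u, v, parent = NULL) {
  if (is.null(parent)) parent <- .parentsFrom(tree, u)
  path <- v
  while (path[1L] != u) path <- c(parent[path[1L]], path)
  path
}

## Median of three vertices: last common vertex of the three pairwise paths.
.medianVertex <- function(tree, x, y, z, adj = NULL) {
  pxy <- .treePath(tree, x, y)
  pxz <- .treePath(tree, x, z)
  ## walk the two paths from x in lockstep; the divergence point is the
  ## median (paths x->y and x->z share a prefix ending at med(x,y,z))
  k <- min(length(pxy), length(pxz))
  i <- 1L
  while (i <= k && pxy[i] == pxz[i]) i <- i + 1L
  pxy[i - 1L]
}

.leafVertex <- function(tree, taxon) {
  v <- tree@leafMap[taxon]
  if (anyNA(v)) stop("unknown taxon: ", paste(taxon[is.na(v)], collapse = ", "))
  unname(v)
}

.taxonOf <- function(tree) {
  ## vertex id -> taxon (NA for interior vertices)
  out <- rep(NA_character_, tree@nVertex)
  out[tree@leafMap] <- names(tree@leafMap)
  out
}

.newUnrootedTree <- function(nVertex, edges, leafMap, mode = TREE_PHYLOGENETIC) {
  storage.mode(edges) <- "integer"
  lm <- as.integer(leafMap)
  names(lm) <- names(leafMap)
  lm <- lm[.sortTaxa(names(lm))]
  new("UnrootedTree", nVertex = as.integer(nVertex), edges = edges,
      leafMap = lm, mode = mode)
}

## Relabel vertices so ids are 1..n' after dropping `drop`; returns
## list(tree-building pieces, map old->new).
.compactVertices <- function(nVertex, edges, keep) {
  map <- integer(nVertex)
  map[keep] <- seq_along(keep)
  e <- cbind(map[edges[, 1L]], map[edges[, 2L]])
  list(map = map, edges = e, n = length(keep))
}

## Suppress all degree-2 vertices of an undirected tree given as an edge
## matrix; returns new edges plus, for each new edge, the full path of old
## vertex ids it replaces.  `protect` vertices are never suppressed.
.suppressDegreeTwo <- function(n, edges, protect = integer(0)) {
  adj <- .adjList(n, edges)
  deg <- lengths(adj)
  suppress <- deg == 2L
  suppress[protect] <- FALSE
  keepV <- which(!suppress)
  newEdges <- matrix(integer(0), ncol = 2L)
  paths <- list()
  visitedEdge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  for (v in keepV) {
    for (w in adj[[v]]) {
      if (!is.null(visitedEdge[[ekey(v, w)]])) next
      ## walk away from v through suppressed vertices
      path <- c(v, w)
      prev <- v; cur <- w
      while (suppress[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        visitedEdge[[ekey(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      visitedEdge[[ekey(v, w)]] <- TRUE
      ## every path edge is now marked, so the same path is never walked
      ## again from the far endpoint: record it once
      newEdges <- rbind(newEdges, c(v, cur))
      paths[[nrow(newEdges)]] <- path
    }
  }
  list(keep = keepV, edges = newEdges, paths = paths)
}
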