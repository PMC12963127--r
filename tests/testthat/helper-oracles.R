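## Independent oracles for the combinatorics under test.  These recompute
## quartets, medians and subdivision counts from first principles (BFS
## distances, the four-point condition) without going through the package's
## split/median machinery.

## adjacency list of an UnrootedTree, derived directly from the edge matrix
.oAdj <- function(tree) {
  adj <- vector("list", tree@nVertex)
  for (i in seq_len(nrow(tree@edges))) {
    u <- tree@edges[i, 1L]
    v <- tree@edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

## BFS distances from vertex s to all vertices
.oDist <- function(adj, n, s) {
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  queue <- s
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(d[w])) {
        d[w] <- d[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  d
}

## BFS path between two vertices (inclusive)
.oPath <- function(adj, n, from, to) {
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    if (v == to) break
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  path <- to
  while (path[1L] != from) path <- c(prev[path[1L]], path)
  path
}

## quartet topologies by the four-point condition on BFS leaf distances:
## among the three pairings of \{a,b,c,d\}, the displayed one is the pairing
## with the strictly smallest distance sum; a tie of all three means the
## restriction is a star (no quartet)
oracleQuartets <- function(tree) {
  taxa <- sort(names(tree@leafMap), method = "radix")
  adj <- .oAdj(tree)
  lv <- tree@leafMap[taxa]
  D <- vapply(lv, function(s) .oDist(adj, tree@nVertex, s),
              integer(tree@nVertex))
  dd <- function(x, y) D[lv[[y]], x]
  out <- character(0)
  for (comb in utils::combn(taxa, 4L, simplify = FALSE)) {
    a <- comb[1L]; b <- comb[2L]; c <- comb[3L]; d <- comb[4L]
    s1 <- dd(a, b) + dd(c, d)
    s2 <- dd(a, c) + dd(b, d)
    s3 <- dd(a, d) + dd(b, c)
    m <- min(s1, s2, s3)
    if (sum(c(s1, s2, s3) == m) > 1L) next
    out <- c(out, if (s1 == m) quartet(a, b, c, d)
             else if (s2 == m) quartet(a, c, b, d)
             else quartet(a, d, b, c))
  }
  sort(out, method = "radix")
}

## median by distance minimization: the unique vertex minimizing
## d(x,.) + d(y,.) + d(z,.)
oracleMedian <- function(tree, x, y, z) {
  adj <- .oAdj(tree)
  tot <- .oDist(adj, tree@nVertex, tree@leafMap[[x]]) +
    .oDist(adj, tree@nVertex, tree@leafMap[[y]]) +
    .oDist(adj, tree@nVertex, tree@leafMap[[z]])
  m <- which(tot == min(tot))
  stopifnot(length(m) == 1L)
  m
}

## subdivision count of a displayed quartet, recomputed from BFS paths
oracleGamma <- function(at, key) {
  tree <- augTree(at)
  tx <- quartetTaxa(key)
  m1 <- oracleMedian(tree, tx[1L], tx[2L], tx[3L])
  m2 <- oracleMedian(tree, tx[3L], tx[4L], tx[1L])
  adj <- .oAdj(tree)
  p <- .oPath(adj, tree@nVertex, m1, m2)
  inner <- p[-c(1L, length(p))]
  sum(augMarks(at)[inner])
}

## the 5-leaf caterpillar with cherries {1,2}, {4,5} and the interior
## vertex adjacent to leaf 3 marked AUG; used across files
caterpillar5 <- function() {
  readAugmentedNewick("((1,2),3,(4,5))AUG;")
}

## names of properties violated in a report
failedProperties <- function(report) {
  v <- reportViolations(report)
  names(v)[lengths(v) > 0L]
}
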