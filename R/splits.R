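## Split and quartet canonicalization plus the split algebra: splits of a
## tree, pairwise compatibility, the split-equivalence construction of the
## tree realizing a compatible system, and split extraction from quartets.

.splitKey <- function(a, b) {
  a <- .sortTaxa(a); b <- .sortTaxa(b)
  if (.sortTaxa(c(a[1L], b[1L]))[1L] != a[1L]) { tmp <- a; a <- b; b <- tmp }
  paste0(paste(a, collapse = ","), "|", paste(b, collapse = ","))
}

.splitParts <- function(key) {
  halves <- strsplit(key, "|", fixed = TRUE)[[1L]]
  list(a = strsplit(halves[1L], ",", fixed = TRUE)[[1L]],
       b = strsplit(halves[2L], ",", fixed = TRUE)[[1L]])
}

#' Canonical quartet tree string
#'
#' Builds the canonical written form \code{"a,b|c,d"} of the quartet tree
#' separating \code{\{a,b\}} from \code{\{c,d\}}: each pair sorted, the
#' pair containing the overall-smallest taxon first.
#'
#' @param a,b,c,d taxon labels; \code{\{a,b\}} and \code{\{c,d\}} are the
#'   two cherries of the quartet.
#' @return character(1), the canonical quartet string.
#' @examples
#' quartet("5", "4", "2", "1")  # "1,2|4,5"
#' @export
quartet <- function(a, b, c, d) {
  .quartetKey(a, b, c, d)
}

.quartetKey <- function(a, b, c, d) {
  if (length(unique(c(a, b, c, d))) != 4L) stop("quartet needs 4 distinct taxa")
  p1 <- .sortTaxa(c(a, b)); p2 <- .sortTaxa(c(c, d))
  if (p2[1L] < p1[1L]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  paste0(p1[1L], ",", p1[2L], "|", p2[1L], ",", p2[2L])
}

#' @describeIn quartet the four taxa of a canonical quartet string, in
#'   written order (pair 1 then pair 2).
#' @param key canonical quartet string.
#' @export
quartetTaxa <- function(key) .quartetTaxa(key)

.quartetTaxa <- function(key) {
  halves <- strsplit(key, "|", fixed = TRUE)[[1L]]
  c(strsplit(halves[1L], ",", fixed = TRUE)[[1L]],
    strsplit(halves[2L], ",", fixed = TRUE)[[1L]])
}

#' Construct a split system
#'
#' @param ground character vector of taxa.
#' @param parts list of two-element lists/character vectors; each element
#'   gives the two parts of one split.  Alternatively \code{splits} may be
#'   passed directly as canonical strings.
#' @param splits character vector of canonical split strings.
#' @return a \linkS4class{SplitSystem}.
#' @export
splitSystem <- function(ground, parts = NULL, splits = NULL) {
  if (is.null(splits)) {
    splits <- vapply(parts, function(p) .splitKey(p[[1L]], p[[2L]]),
                     character(1))
  }
  new("SplitSystem", ground = .sortTaxa(ground),
      splits = unique(splits))
}

#' Splits displayed by a phylogenetic tree
#'
#' Deleting an edge of a phylogenetic tree splits the leaf set into the two
#' parts of a full split; one split per edge, trivial splits corresponding
#' to the leaf edges.
#'
#' @param tree a phylogenetic \linkS4class{UnrootedTree}.
#' @param trivial keep the trivial (leaf-edge) splits? Default TRUE.
#' @return a \linkS4class{SplitSystem} with one split per (kept) edge.
#' @export
treeSplits <- function(tree, trivial = TRUE) {
  stopifnot(is(tree, "UnrootedTree"))
  if (tree@mode != TREE_PHYLOGENETIC) stop("tree must be phylogenetic")
  taxa <- names(tree@leafMap)
  n <- tree@nVertex
  edges <- tree@edges
  taxonOf <- .taxonOf(tree)
  ## leaf sets below each edge via rooting at vertex 1
  adj <- .adjList(n, edges)
  parent <- .parentsFrom(tree, 1L, adj)
  ## postorder accumulation of leaf sets per vertex
  order <- integer(0)
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    stack <- c(stack, setdiff(adj[[v]], parent[v]))
  }
  below <- vector("list", n)
  for (v in rev(order)) {
    kids <- setdiff(adj[[v]], parent[v])
    s <- if (is.na(taxonOf[v])) character(0) else taxonOf[v]
    for (k in kids) s <- c(s, below[[k]])
    below[[v]] <- s
  }
  keys <- character(0)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    child <- if (parent[v] == u) v else u
    a <- below[[child]]
    b <- setdiff(taxa, a)
    if (!trivial && (length(a) == 1L || length(b) == 1L)) next
    keys <- c(keys, .splitKey(a, b))
  }
  splitSystem(taxa, splits = keys)
}

#' Pairwise compatibility of a split system
#'
#' Two full splits are compatible when some part of one is disjoint from
#' some part of the other; a system is compatible when every pair is.
#' Compatible systems containing all trivial splits are exactly those
#' realized by a phylogenetic tree.
#'
#' @param system a \linkS4class{SplitSystem} of full splits.
#' @return logical(1).
#' @export
isCompatible <- function(system) {
  stopifnot(is(system, "SplitSystem"))
  parts <- lapply(system@splits, .splitParts)
  g <- system@ground
  for (p in parts) {
    if (length(p$a) + length(p$b) != length(g)) {
      stop("partial split present; compatibility is defined for full splits")
    }
  }
  k <- length(parts)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pi <- parts[[i]]; pj <- parts[[j]]
      ok <- !length(intersect(pi$a, pj$a)) || !length(intersect(pi$a, pj$b)) ||
        !length(intersect(pi$b, pj$a)) || !length(intersect(pi$b, pj$b))
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

#' Tree realizing a compatible split system
#'
#' Inverts \code{\link{treeSplits}}: given a compatible system of full
#' splits containing every trivial split of its ground set, builds the
#' unique phylogenetic tree displaying exactly those splits.  Works by
#' rooting the system at the smallest taxon: the parts avoiding it form a
#' laminar family whose containment forest is the tree.
#'
#' @param system a \linkS4class{SplitSystem}.
#' @return an \linkS4class{UnrootedTree}.
#' @export
treeFromSplits <- function(system) {
  stopifnot(is(system, "SplitSystem"))
  g <- system@ground
  if (length(g) < 2L) stop("need at least two taxa")
  parts <- lapply(system@splits, .splitParts)
  for (p in parts) {
    if (length(p$a) + length(p$b) != length(g)) stop("partial split present")
  }
  ## check all trivial splits present
  triv <- vapply(g, function(x) .splitKey(x, setdiff(g, x)), character(1))
  if (!all(triv %in% system@splits)) stop("missing trivial split")
  if (length(g) == 2L) {
    return(.newUnrootedTree(2L, cbind(1L, 2L),
                            structure(1:2, names = g)))
  }
  x0 <- g[1L]
  ## clusters: for each split, the part avoiding x0; drop the cluster of the
  ## trivial split isolating x0 (it is the pendant edge of x0 itself)
  clusters <- lapply(parts, function(p) if (x0 %in% p$a) p$b else p$a)
  clusters <- unique(clusters[lengths(clusters) < length(g) - 1L |
                                vapply(clusters, function(cl)
                                  length(cl) == 1L, logical(1))])
  clusters <- unique(c(clusters, as.list(setdiff(g, x0))))
  ## laminar check (equivalent to compatibility for splits sharing x0-part)
  k <- length(clusters)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        int <- length(intersect(clusters[[i]], clusters[[j]]))
        if (int && int != min(length(clusters[[i]]), length(clusters[[j]]))) {
          stop("incompatible split system")
        }
        if (int == length(clusters[[i]]) && int == length(clusters[[j]])) {
          stop("incompatible split system")  # duplicates survived unique()?
        }
      }
    }
  }
  ## build containment forest: parent = smallest strictly containing cluster
  sizes <- lengths(clusters)
  ord <- order(sizes, decreasing = TRUE)
  nClust <- length(clusters)
  nV <- nClust + 2L  # + root vertex + leaf x0
  rootV <- nClust + 1L
  x0V <- nClust + 2L
  parentOf <- rep(rootV, nClust)
  for (ii in seq_len(nClust)) {
    ci <- clusters[[ii]]
    best <- 0L; bestSize <- Inf
    for (jj in seq_len(nClust)) {
      if (jj == ii) next
      cj <- clusters[[jj]]
      if (length(cj) > length(ci) && all(ci %in% cj) && length(cj) < bestSize) {
        best <- jj; bestSize <- length(cj)
      }
    }
    if (best) parentOf[ii] <- best
  }
  edges <- cbind(seq_len(nClust), parentOf)
  edges <- rbind(edges, c(x0V, rootV))
  leafMap <- integer(0)
  singles <- which(sizes == 1L)
  lm <- vapply(singles, function(i) i, integer(1))
  names(lm) <- vapply(singles, function(i) clusters[[i]][1L], character(1))
  lm <- c(lm, structure(x0V, names = x0))
  tr <- .newUnrootedTree(nV, edges, lm)
  out <- validObject(tr)
  ## sanity: realized splits must equal the input
  realized <- treeSplits(tr)
  if (!setequal(realized@splits, system@splits)) {
    stop("incompatible split system")
  }
  tr
}

#' Full splits supported by a quartet system
#'
#' Recovers the full splits A|B of the ground set for which every
#' cross-quartet a1,a2|b1,b2 (a's from A, b's from B) lies in the input.
#' Each input quartet's pair sets are greedily extended, scanning taxa in
#' lexicographic order and adding a taxon to the first side whose
#' cross-quartets are all present, until no taxon can be added; only
#' extensions covering the whole ground set are kept.  For the displayed
#' quartet set of a tree this recovers exactly the tree's non-trivial
#' splits.
#'
#' @param quartets character vector of canonical quartet strings.
#' @param ground character vector of taxa (>= 4).
#' @return a \linkS4class{SplitSystem} of non-trivial full splits.
#' @export
splitsFromQuartets <- function(quartets, ground) {
  ground <- .sortTaxa(ground)
  if (length(ground) < 4L) stop("ground set must have >= 4 taxa")
  have <- new.env(hash = TRUE)
  for (q in quartets) assign(q, TRUE, envir = have)
  hasQ <- function(a1, a2, b1, b2)
    !is.null(have[[.quartetKey(a1, a2, b1, b2)]])
  crossOK <- function(x, A, B) {
    ## all quartets x,a|b1,b2 present
    if (length(B) < 2L) return(TRUE)
    for (a in A) {
      for (i in seq_len(length(B) - 1L)) {
        for (j in (i + 1L):length(B)) {
          if (!hasQ(x, a, B[i], B[j])) return(FALSE)
        }
      }
    }
    TRUE
  }
  found <- character(0)
  for (q in quartets) {
    tx <- .quartetTaxa(q)
    A <- tx[1:2]; B <- tx[3:4]
    repeat {
      grew <- FALSE
      for (x in setdiff(ground, c(A, B))) {
        if (crossOK(x, A, B)) { A <- c(A, x); grew <- TRUE }
        else if (crossOK(x, B, A)) { B <- c(B, x); grew <- TRUE }
      }
      if (!grew) break
    }
    if (length(A) + length(B) == length(ground)) {
      found <- c(found, .splitKey(A, B))
    }
  }
  splitSystem(ground, splits = unique(found))
}

## quartets displayed by a full split A|B: all a1,a2|b1,b2
.splitQuartets <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(character(0))
  out <- character(0)
  ca <- utils::combn(a, 2L)
  cb <- utils::combn(b, 2L)
  for (i in seq_len(ncol(ca))) {
    for (j in seq_len(ncol(cb))) {
      out <- c(out, .quartetKey(ca[1L, i], ca[2L, i], cb[1L, j], cb[2L, j]))
    }
  }
  out
}
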