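## Orientation of a binary augmented tree on X-and-root-handles into a
## multi-rooted arboreal network, or a certificate that none exists.
##
## The published procedure is reconstructed here as a contraction followed
## by deterministic constraint propagation on the full tree: boundary
## conditions (handle edges point away from handles, taxon-leaf edges
## point into leaves, pruned subtrees point away from the retained core)
## plus the per-vertex degree profiles -- AUG vertices are reticulations
## and need (in 2, out 1), interior PLAIN vertices need (in 1, out 2) --
## force every remaining edge one by one.  The cherry-by-cherry reduction
## that the original description walks through is subsumed: each cherry
## step is exactly one propagation step, and on a tree the propagation
## never stalls (an undirected residual subforest always has an endpoint
## vertex with two decided edges).  Orientations are therefore unique when
## they exist, and the order of forced steps cannot change the outcome.

ORIENT_IN <- "IN"
ORIENT_OUT <- "OUT"
ORIENT_INFEASIBLE <- "INFEASIBLE"
ORIENT_SATISFIED <- "SATISFIED"
ORIENT_UNDETERMINED <- "UNDETERMINED"

FAIL_PRUNE_STRANDED_AUG <- "PRUNE_STRANDED_AUG"
FAIL_VERTEX_INFEASIBLE <- "VERTEX_INFEASIBLE"
FAIL_ENDGAME_CONFLICT <- "ENDGAME_CONFLICT"
FAIL_POST_VALIDATION <- "POST_VALIDATION"

#' Forced direction of a binary interior vertex's remaining edge
#'
#' A binary interior vertex of the orientation problem must end with arc
#' profile (in, out) = (2, 1) if AUG (a reticulation) and (1, 2) if PLAIN.
#' Given the directions already decided at the vertex, returns what that
#' implies.
#'
#' @param mark \code{"PLAIN"} or \code{"AUG"}.
#' @param nIn,nOut counts of already-decided incoming/outgoing edges
#'   (nIn + nOut <= 3).
#' @return \code{"IN"} or \code{"OUT"} (two edges decided, third forced);
#'   \code{"SATISFIED"} (all three decided, profile met);
#'   \code{"INFEASIBLE"} (profile already violated);
#'   \code{"UNDETERMINED"} (fewer than two decided, nothing forced).
#' @examples
#' forcedDirection("AUG", 1, 1)    # "IN"
#' forcedDirection("PLAIN", 1, 1)  # "OUT"
#' forcedDirection("AUG", 0, 2)    # "INFEASIBLE"
#' @export
forcedDirection <- function(mark, nIn, nOut) {
  stopifnot(mark %in% c(MARK_PLAIN, MARK_AUG), nIn >= 0L, nOut >= 0L,
            nIn + nOut <= 3L)
  tIn <- if (mark == MARK_AUG) 2L else 1L
  tOut <- 3L - tIn
  if (nIn > tIn || nOut > tOut) return(ORIENT_INFEASIBLE)
  known <- nIn + nOut
  if (known == 3L) return(ORIENT_SATISFIED)
  if (known < 2L) return(ORIENT_UNDETERMINED)
  if (nIn < tIn) ORIENT_IN else ORIENT_OUT
}

## ---- shared plumbing ------------------------------------------------

.checkOrientInput <- function(t, X, R, rho) {
  stopifnot(is(t, "AugmentedTree"))
  tr <- t@tree
  taxa <- names(tr@leafMap)
  if (length(intersect(X, R))) stop("X and R must be disjoint")
  if (!setequal(c(X, R), taxa)) stop("X and R must partition the leaf taxa")
  if (!length(R)) stop("R must be nonempty")
  deg <- .degrees(tr)
  if (any(!deg %in% c(1L, 3L))) stop("tree must be binary (no degree-2 vertices, interior degree 3)")
  if (is.null(rho)) rho <- .sortTaxa(R)[1L]
  if (!rho %in% R) stop("rho must be one of the root taxa")
  rho
}

## rows of `edges` incident to each vertex
.incidentEdges <- function(n, edges) {
  inc <- vector("list", n)
  for (i in seq_len(n)) inc[[i]] <- integer(0)
  for (i in seq_len(nrow(edges))) {
    inc[[edges[i, 1L]]] <- c(inc[[edges[i, 1L]]], i)
    inc[[edges[i, 2L]]] <- c(inc[[edges[i, 2L]]], i)
  }
  inc
}

## dir encoding per edge row: 0 unset, 1 = col1 -> col2, 2 = col2 -> col1
.edgeHead <- function(edges, i, d) if (d == 1L) edges[i, 2L] else edges[i, 1L]

.dirToward <- function(edges, i, v) if (edges[i, 2L] == v) 1L else 2L

.orientFailure <- function(code, witness = integer(0)) {
  new("OrientResult", success = FALSE, network = NULL, code = code,
      witness = as.integer(witness))
}

#' Contract a binary augmented tree to its orientation core
#'
#' Computes the retained core of the orientation problem: the span of the
#' root handles, the AUG vertices, and the X-leaves adjacent to AUG
#' vertices.  Edges outside the span are directed away from it (towards
#' the pruned leaves) in the returned partial orientation; PLAIN span
#' vertices of degree two are suppressed, with \code{tau} recording the
#' replaced input-tree paths.  An AUG vertex left with fewer than two span
#' neighbours cannot reach the reticulation profile (two of its edges
#' already point out), so the contraction is returned failure-tagged.
#'
#' @param t a binary phylogenetic \linkS4class{AugmentedTree} on the taxa
#'   X union R.
#' @param X,R character vectors partitioning the leaf taxa: ordinary taxa
#'   and root-handle names.
#' @param rho character(1), the reference handle; default the smallest
#'   element of R.
#' @return a \linkS4class{CoreContraction}.
#' @export
contractToCore <- function(t, X, R, rho = NULL) {
  rho <- .checkOrientInput(t, X, R, rho)
  tr <- t@tree
  n <- tr@nVertex
  edges <- tr@edges
  adj <- .adjList(n, edges)
  deg <- lengths(adj)
  inc <- .incidentEdges(n, edges)
  xv <- .leafVertex(tr, X)
  rv <- .leafVertex(tr, R)
  augV <- which(t@aug)
  ## X-leaves adjacent to an AUG vertex
  la <- xv[vapply(xv, function(v) t@aug[adj[[v]][1L]], logical(1))]
  terminals <- unique(c(rv, augV, la))
  rhoV <- .leafVertex(tr, rho)

  inSpan <- logical(n)
  parent <- .parentsFrom(tr, rhoV, adj)
  for (v in terminals) {
    while (v != 0L && !inSpan[v]) { inSpan[v] <- TRUE; v <- parent[v] }
  }

  ## prune: direct every non-span edge away from the span
  partial <- integer(nrow(edges))
  seen <- inSpan
  queue <- which(inSpan)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (i in inc[[v]]) {
      w <- if (edges[i, 1L] == v) edges[i, 2L] else edges[i, 1L]
      if (!seen[w]) {
        seen[w] <- TRUE
        partial[i] <- if (edges[i, 1L] == v) 1L else 2L
        queue <- c(queue, w)
      }
    }
  }

  failedCore <- function(code, witness) {
    new("CoreContraction",
        core = new("AugmentedTree",
                   tree = .newUnrootedTree(1L, matrix(integer(0), ncol = 2L),
                                           structure(1L, names = rho)),
                   aug = FALSE),
        coreVertexOf = rhoV, tau = list(), partial = partial, rho = rho,
        failed = TRUE, failCode = code)
  }

  spanDeg <- vapply(seq_len(n), function(v)
    if (inSpan[v]) sum(inSpan[adj[[v]]]) else 0L, integer(1))
  stranded <- augV[spanDeg[augV] <= 1L]
  if (length(stranded)) {
    return(failedCore(FAIL_PRUNE_STRANDED_AUG))
  }

  spanV <- which(inSpan)
  spanEdges <- edges[inSpan[edges[, 1L]] & inSpan[edges[, 2L]], , drop = FALSE]
  cp <- .compactVertices(n, spanEdges, spanV)
  if (cp$n == 1L) {
    core <- new("AugmentedTree",
                tree = .newUnrootedTree(1L, matrix(integer(0), ncol = 2L),
                                        structure(1L, names = rho)),
                aug = FALSE)
    return(new("CoreContraction", core = core, coreVertexOf = rhoV,
               tau = list(), partial = partial, rho = rho, failed = FALSE,
               failCode = NA_character_))
  }
  sup <- .suppressDegreeTwo(cp$n, cp$edges, protect = cp$map[augV])
  cp2 <- .compactVertices(cp$n, sup$edges, sup$keep)
  ## core vertex id -> original vertex id
  coreVertexOf <- spanV[match(seq_len(cp2$n), cp2$map[cp$map[spanV]])]
  leafTaxa <- intersect(names(tr@leafMap), c(R, names(tr@leafMap)[match(la, tr@leafMap)]))
  coreLm <- structure(cp2$map[cp$map[.leafVertex(tr, leafTaxa)]],
                      names = leafTaxa)
  coreDeg <- tabulate(as.integer(cp2$edges), nbins = cp2$n)
  mode <- if (any(coreDeg == 2L)) TREE_PARTIALLY_SUBDIVIDED else TREE_PHYLOGENETIC
  coreTree <- .newUnrootedTree(cp2$n, cp2$edges, coreLm, mode = mode)
  validObject(coreTree)
  core <- new("AugmentedTree", tree = coreTree, aug = t@aug[coreVertexOf])
  validObject(core)
  ## tau: per core edge, the original-vertex path it stands for
  spanId <- spanV                       # compacted span id -> original id
  tau <- lapply(sup$paths, function(p) spanId[p])
  new("CoreContraction", core = core, coreVertexOf = as.integer(coreVertexOf),
      tau = tau, partial = partial, rho = rho, failed = FALSE,
      failCode = NA_character_)
}

## Build and validate the network for a full orientation `dir` of t's
## edges; returns an OrientResult.
.finishOrientation <- function(t, X, R, dir) {
  tr <- t@tree
  edges <- tr@edges
  stopifnot(all(dir %in% 1:2))
  tails <- ifelse(dir == 1L, edges[, 1L], edges[, 2L])
  heads <- ifelse(dir == 1L, edges[, 2L], edges[, 1L])
  rv <- .leafVertex(tr, R)
  taxonOf <- .taxonOf(tr)
  out <- tryCatch({
    handleArc <- which(tails %in% rv)
    if (length(handleArc) != length(rv)) stop("handle edge directed into its handle")
    rootV <- heads[handleArc]
    handleOf <- structure(taxonOf[tails[handleArc]], names = rootV)
    keepArc <- !(tails %in% rv | heads %in% rv)
    keepV <- setdiff(seq_len(tr@nVertex), rv)
    map <- integer(tr@nVertex)
    map[keepV] <- seq_along(keepV)
    net <- arborealNetwork(length(keepV),
                           cbind(map[tails[keepArc]], map[heads[keepArc]]),
                           structure(map[.leafVertex(tr, X)], names = X))
    roots <- networkRoots(net)
    if (!setequal(roots, map[rootV])) stop("root set mismatch")
    handles <- unname(handleOf[as.character(keepV[roots])])
    ua <- underlyingAugmented(net, handles = handles)
    if (!augmentationEquivalent(ua$tree, t)) {
      stop("underlying augmented tree differs from the input")
    }
    net
  }, error = function(e) e)
  if (inherits(out, "error")) {
    .orientFailure(FAIL_POST_VALIDATION)
  } else {
    new("OrientResult", success = TRUE, network = out,
        code = NA_character_, witness = integer(0))
  }
}

#' Orient a binary augmented tree into an arboreal network
#'
#' Decides whether the augmented tree t on the taxa X union R can be
#' turned into an arboreal network on X whose root set corresponds to the
#' handles R, with the AUG vertices becoming exactly the reticulations.
#' The orientation, when it exists, is unique; on failure a code and a
#' witness vertex set are reported (\code{"PRUNE_STRANDED_AUG"}: an AUG
#' vertex loses two subtrees to pruning; \code{"VERTEX_INFEASIBLE"}: a
#' vertex's degree profile cannot be met; \code{"ENDGAME_CONFLICT"}: two
#' vertices force the same edge both ways; \code{"POST_VALIDATION"}: the
#' fully directed tree is not a valid network on the requested roots).
#'
#' @param t a binary phylogenetic \linkS4class{AugmentedTree} on X union R.
#' @param X,R character vectors partitioning the leaf taxa.
#' @param rho character(1), reference handle (outcome-irrelevant; default
#'   smallest element of R).
#' @return an \linkS4class{OrientResult}.
#' @examples
#' t <- readAugmentedNewick("((R1,a),b,c);")
#' res <- checkOrient(t, X = c("a", "b", "c"), R = "R1")
#' orientSuccess(res)
#' @export
checkOrient <- function(t, X, R, rho = NULL) {
  rho <- .checkOrientInput(t, X, R, rho)
  tr <- t@tree
  n <- tr@nVertex
  edges <- tr@edges
  adj <- .adjList(n, edges)
  inc <- .incidentEdges(n, edges)
  deg <- lengths(adj)
  xv <- .leafVertex(tr, X)
  rv <- .leafVertex(tr, R)

  ## fast pre-check: an AUG vertex next to two X-leaves would need two
  ## outgoing leaf edges on top of its single permitted out-arc
  for (v in which(t@aug)) {
    if (sum(adj[[v]] %in% xv) >= 2L) {
      return(.orientFailure(FAIL_VERTEX_INFEASIBLE, v))
    }
  }

  cc <- contractToCore(t, X, R, rho)
  if (cc@failed) return(.orientFailure(cc@failCode))
  dir <- cc@partial

  ## boundary conditions at the leaves
  for (v in rv) {
    i <- inc[[v]][1L]
    d <- .dirToward(edges, i, adj[[v]][1L])   # away from the handle
    if (dir[i] == 0L) dir[i] <- d
    else if (dir[i] != d) return(.orientFailure(FAIL_ENDGAME_CONFLICT, v))
  }
  for (v in xv) {
    i <- inc[[v]][1L]
    d <- .dirToward(edges, i, v)              # into the taxon leaf
    if (dir[i] == 0L) dir[i] <- d
    else if (dir[i] != d) return(.orientFailure(FAIL_ENDGAME_CONFLICT, v))
  }

  markOf <- function(v) if (t@aug[v]) MARK_AUG else MARK_PLAIN
  counts <- function(v) {
    ins <- 0L; outs <- 0L; unset <- integer(0)
    for (i in inc[[v]]) {
      d <- dir[i]
      if (d == 0L) unset <- c(unset, i)
      else if (.edgeHead(edges, i, d) == v) ins <- ins + 1L
      else outs <- outs + 1L
    }
    list(ins = ins, outs = outs, unset = unset)
  }

  interior <- which(deg == 3L)
  active <- interior                     # kept sorted: deterministic order
  while (length(active)) {
    v <- active[1L]; active <- active[-1L]
    ct <- counts(v)
    fd <- forcedDirection(markOf(v), ct$ins, ct$outs)
    if (fd == ORIENT_INFEASIBLE) {
      return(.orientFailure(FAIL_VERTEX_INFEASIBLE, v))
    }
    if (fd %in% c(ORIENT_IN, ORIENT_OUT)) {
      i <- ct$unset[1L]
      u <- if (edges[i, 1L] == v) edges[i, 2L] else edges[i, 1L]
      d <- if (fd == ORIENT_IN) .dirToward(edges, i, v) else .dirToward(edges, i, u)
      ## if the other endpoint also pins this edge, the two forcings must
      ## agree
      if (deg[u] == 3L) {
        ctu <- counts(u)
        if (length(ctu$unset) == 1L) {
          fdu <- forcedDirection(markOf(u), ctu$ins, ctu$outs)
          if (fdu == ORIENT_INFEASIBLE) {
            return(.orientFailure(FAIL_VERTEX_INFEASIBLE, u))
          }
          du <- if (fdu == ORIENT_IN) .dirToward(edges, i, u) else .dirToward(edges, i, v)
          if (du != d) {
            return(.orientFailure(FAIL_ENDGAME_CONFLICT, c(v, u)))
          }
        }
      }
      dir[i] <- d
      if (deg[u] == 3L && !(u %in% active)) {
        active <- sort(c(active, u))
      }
    }
  }
  ## on a tree the propagation cannot stall
  stopifnot(all(dir %in% 1:2))
  ## final per-vertex audit
  for (v in interior) {
    ct <- counts(v)
    if (forcedDirection(markOf(v), ct$ins, ct$outs) != ORIENT_SATISFIED) {
      return(.orientFailure(FAIL_VERTEX_INFEASIBLE, v))
    }
  }
  .finishOrientation(t, X, R, dir)
}

#' Accessors for orientation results
#'
#' @param res an \linkS4class{OrientResult}.
#' @return \code{orientSuccess}: logical(1); \code{orientNetwork}: the
#'   \linkS4class{ArborealNetwork} (NULL on failure); \code{orientCode}:
#'   the failure code or NA; \code{orientWitness}: integer vertex ids.
#' @export
orientSuccess <- function(res) { stopifnot(is(res, "OrientResult")); res@success }

#' @rdname orientSuccess
#' @export
orientNetwork <- function(res) { stopifnot(is(res, "OrientResult")); res@network }

#' @rdname orientSuccess
#' @export
orientCode <- function(res) { stopifnot(is(res, "OrientResult")); res@code }

#' @rdname orientSuccess
#' @export
orientWitness <- function(res) { stopifnot(is(res, "OrientResult")); res@witness }

#' Exhaustive orientation oracle
#'
#' Enumerates every orientation of the tree's edges that satisfies the
#' boundary conditions (handle edges away from handles, taxon-leaf edges
#' into leaves) and the interior degree profiles, then keeps those that
#' also pass the full network validation.  Independent of
#' \code{\link{checkOrient}}'s propagation; intended as a testing oracle.
#'
#' @inheritParams checkOrient
#' @return list of \linkS4class{ArborealNetwork} objects (length 0 or,
#'   when the instance is orientable, 1).
#' @export
bruteForceOrient <- function(t, X, R) {
  .checkOrientInput(t, X, R, NULL)
  tr <- t@tree
  if (length(tr@leafMap) > 16L) stop("brute force capped at 16 leaves")
  edges <- tr@edges
  n <- tr@nVertex
  adj <- .adjList(n, edges)
  deg <- lengths(adj)
  inc <- .incidentEdges(n, edges)
  xv <- .leafVertex(tr, X)
  rv <- .leafVertex(tr, R)
  base <- integer(nrow(edges))
  for (v in rv) base[inc[[v]][1L]] <- .dirToward(edges, inc[[v]][1L], adj[[v]][1L])
  for (v in xv) base[inc[[v]][1L]] <- .dirToward(edges, inc[[v]][1L], v)
  free <- which(base == 0L)
  m <- length(free)
  found <- list()
  interior <- which(deg == 3L)
  for (code in 0:(2^m - 1L)) {
    dir <- base
    if (m) dir[free] <- 1L + bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L)
    ok <- TRUE
    for (v in interior) {
      ins <- 0L
      for (i in inc[[v]]) if (.edgeHead(edges, i, dir[i]) == v) ins <- ins + 1L
      want <- if (t@aug[v]) 2L else 1L
      if (ins != want) { ok <- FALSE; break }
    }
    if (!ok) next
    res <- .finishOrientation(t, X, R, dir)
    if (res@success) found[[length(found) + 1L]] <- res@network
  }
  found
}

#' Detect the forbidden configuration that blocks orientation
#'
#' Searches for connected sets C of interior PLAIN vertices without leaf
#' neighbours whose entire boundary consists of AUG vertices each adjacent
#' to exactly one X-leaf.  Every edge leaving such a component must point
#' into it (each boundary AUG vertex spends its out-arc on its leaf), so
#' some vertex of C ends up with too many incoming arcs: any witness
#' implies orientation failure.  The test is sufficient, not necessary.
#'
#' @inheritParams checkOrient
#' @return list of integer vectors, the witness components' vertex ids.
#' @export
detectForbiddenConfiguration <- function(t, X, R) {
  .checkOrientInput(t, X, R, NULL)
  tr <- t@tree
  n <- tr@nVertex
  adj <- .adjList(n, tr@edges)
  deg <- lengths(adj)
  xv <- .leafVertex(tr, X)
  isCand <- vapply(seq_len(n), function(v) {
    deg[v] == 3L && !t@aug[v] && !any(deg[adj[[v]]] == 1L)
  }, logical(1))
  seen <- logical(n)
  out <- list()
  for (s in which(isCand)) {
    if (seen[s]) next
    comp <- integer(0); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (isCand[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    boundary <- setdiff(unique(unlist(adj[comp])), comp)
    good <- vapply(boundary, function(b) {
      t@aug[b] && sum(adj[[b]] %in% xv) == 1L
    }, logical(1))
    if (all(good)) out[[length(out) + 1L]] <- sort(comp)
  }
  out
}
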