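#' @import methods
NULL

## Vertex-mark constants used throughout: interior vertices of augmented
## trees carry PLAIN ("circle") or AUG ("bullet") marks; AUG marks record
## reticulation vertices when the tree underlies an arboreal network.
MARK_PLAIN <- "PLAIN"
MARK_AUG <- "AUG"

TREE_PHYLOGENETIC <- "PHYLOGENETIC"
TREE_PARTIALLY_SUBDIVIDED <- "PARTIALLY_SUBDIVIDED"

.validTaxon <- function(x) {
  is.character(x) & nzchar(x) & !grepl("[\\s()\\[\\],:;]", x, perl = TRUE) &
    grepl("^[A-Za-z0-9_.^-]+$", x)
}

#' Unrooted leaf-labelled tree
#'
#' An unrooted tree whose degree-one vertices (and only those) carry taxon
#' labels.  Vertices are opaque integer ids \code{1..nVertex}; \code{edges}
#' is an (nVertex-1) x 2 integer matrix of unordered vertex pairs;
#' \code{leafMap} is a named integer vector mapping taxa to leaf vertex ids.
#' In \code{PHYLOGENETIC} mode no vertex has degree two; in
#' \code{PARTIALLY_SUBDIVIDED} mode degree-two vertices (subdivision points)
#' are allowed but never adjacent to a leaf.
#'
#' @slot nVertex integer(1), number of vertices.
#' @slot edges integer matrix with two columns, one row per edge.
#' @slot leafMap named integer vector, taxon label to leaf vertex id.
#' @slot mode \code{"PHYLOGENETIC"} or \code{"PARTIALLY_SUBDIVIDED"}.
#' @exportClass UnrootedTree
setClass("UnrootedTree",
  representation(
    nVertex = "integer",
    edges = "matrix",
    leafMap = "integer",
    mode = "character"
  )
)

setValidity("UnrootedTree", function(object) {
  n <- object@nVertex
  e <- object@edges
  if (n < 1L) return("tree must have at least one vertex")
  if (n == 1L) {
    if (nrow(e) != 0L) return("single-vertex tree cannot have edges")
    if (length(object@leafMap) != 1L || object@leafMap != 1L) {
      return("single-vertex tree must carry exactly one taxon")
    }
    if (!all(.validTaxon(names(object@leafMap)))) {
      return("invalid taxon label")
    }
    return(TRUE)
  }
  if (nrow(e) != n - 1L) return("edge count must be nVertex - 1")
  if (any(e < 1L) || any(e > n)) return("edge endpoint out of range")
  if (any(e[, 1L] == e[, 2L])) return("self-loop edge")
  deg <- tabulate(as.integer(e), nbins = n)
  if (!.allConnected(n, e)) return("tree is not connected")
  lv <- which(deg == 1L)
  lm <- object@leafMap
  taxa <- names(lm)
  if (length(lm) != length(lv) || !setequal(lm, lv)) {
    return("leafMap must map taxa onto the degree-one vertices, bijectively")
  }
  if (anyDuplicated(taxa) || anyDuplicated(lm)) {
    return("duplicate taxon label or leaf vertex")
  }
  if (!all(.validTaxon(taxa))) return("invalid taxon label")
  d2 <- which(deg == 2L)
  if (object@mode == TREE_PHYLOGENETIC) {
    if (length(d2)) return("degree-two vertex in PHYLOGENETIC mode")
  } else if (object@mode != TREE_PARTIALLY_SUBDIVIDED) {
    return("unknown tree mode")
  }
  ## NB: "no subdivision point adjacent to a leaf" is enforced by the
  ## public constructors/readers (.assertNoLeafSubdivision), not here: the
  ## orientation algorithm's core contraction legitimately produces
  ## leaf-adjacent degree-2 augmentation points next to root handles.
  TRUE
})

.assertNoLeafSubdivision <- function(tree) {
  deg <- .degrees(tree)
  d2 <- which(deg == 2L)
  if (length(d2)) {
    adj <- .adjList(tree@nVertex, tree@edges)
    for (v in d2) {
      if (any(deg[adj[[v]]] == 1L)) {
        stop("subdivision point adjacent to a leaf")
      }
    }
  }
  invisible(tree)
}

#' Split system on a fixed ground set
#'
#' Splits are kept in the canonical text form \code{"a,b|c,d,e"}: taxa
#' within a part sorted (C locale), and the part containing the smallest
#' taxon written first.  Partial splits (parts not covering the ground set)
#' are representable; most operations require full splits.
#'
#' @slot ground character vector of taxa (sorted).
#' @slot splits character vector of canonical split strings.
#' @exportClass SplitSystem
setClass("SplitSystem",
  representation(ground = "character", splits = "character")
)

setValidity("SplitSystem", function(object) {
  g <- object@ground
  if (anyDuplicated(g)) return("duplicate taxon in ground set")
  if (!identical(g, .sortTaxa(g))) return("ground set must be sorted")
  for (s in object@splits) {
    p <- .splitParts(s)
    if (!all(c(p$a, p$b) %in% g)) return("split taxon outside ground set")
    if (length(intersect(p$a, p$b))) return("split parts overlap")
    if (!length(p$a) || !length(p$b)) return("empty split part")
    if (.splitKey(p$a, p$b) != s) return("non-canonical split string")
  }
  if (anyDuplicated(object@splits)) return("duplicate split")
  TRUE
})

#' Augmented tree
#'
#' An unrooted tree together with a vertex marking: interior vertices may be
#' AUG (augmentation vertices; reticulations when the tree underlies an
#' arboreal network).  Leaves are always PLAIN and subdivision points are
#' always AUG (augmentation points).
#'
#' @slot tree an \linkS4class{UnrootedTree}.
#' @slot aug logical vector of length nVertex; TRUE = AUG.
#' @exportClass AugmentedTree
setClass("AugmentedTree",
  representation(tree = "UnrootedTree", aug = "logical")
)

setValidity("AugmentedTree", function(object) {
  tr <- object@tree
  a <- object@aug
  if (length(a) != tr@nVertex) return("aug length must equal vertex count")
  if (anyNA(a)) return("aug marks must be TRUE/FALSE")
  deg <- .degrees(tr)
  if (any(a[deg == 1L])) return("leaf marked AUG")
  if (any(!a[deg == 2L])) return("subdivision point not marked AUG")
  TRUE
})

#' Enhanced quartet tree system
#'
#' Stores a subdivision map gamma over quartet trees (quartets absent from
#' the table have gamma = -1) together with the marks of the two medians of
#' each supported quartet.  Quartets are canonical strings \code{"a,b|c,d"}
#' (pairs sorted, pair holding the overall-smallest taxon first);
#' \code{nuNear}/\code{nuFar} are the marks of the pair-1-side and
#' pair-2-side medians.
#'
#' @slot ground character vector of taxa (sorted, length >= 4).
#' @slot quartets character vector of canonical quartet strings.
#' @slot gamma integer vector (>= 0), aligned with \code{quartets}.
#' @slot nuNear,nuFar character vectors of \code{"PLAIN"}/\code{"AUG"} marks.
#' @exportClass EnhancedQuartetSystem
setClass("EnhancedQuartetSystem",
  representation(
    ground = "character",
    quartets = "character",
    gamma = "integer",
    nuNear = "character",
    nuFar = "character"
  )
)

setValidity("EnhancedQuartetSystem", function(object) {
  g <- object@ground
  if (length(g) < 4L) return("ground set must have at least 4 taxa")
  if (!identical(g, .sortTaxa(g))) return("ground set must be sorted")
  q <- object@quartets
  if (!length(q)) return("support must be nonempty")
  if (anyDuplicated(q)) return("duplicate quartet")
  k <- length(q)
  if (length(object@gamma) != k || length(object@nuNear) != k ||
      length(object@nuFar) != k) {
    return("gamma/nuNear/nuFar must align with quartets")
  }
  if (any(object@gamma < 0L)) return("gamma must be >= 0 for stored quartets")
  if (!all(object@nuNear %in% c(MARK_PLAIN, MARK_AUG)) ||
      !all(object@nuFar %in% c(MARK_PLAIN, MARK_AUG))) {
    return("marks must be PLAIN or AUG")
  }
  for (s in q) {
    tx <- .quartetTaxa(s)
    if (!all(tx %in% g)) return("quartet taxon outside ground set")
    if (.quartetKey(tx[1L], tx[2L], tx[3L], tx[4L]) != s) {
      return("non-canonical quartet string")
    }
  }
  TRUE
})

#' Report of the six characteristic properties
#'
#' One witness list per property (A1..A6); \code{allPass} is TRUE iff every
#' list is empty.  Witnesses are short character descriptions of the taxa
#' involved and the reason.
#'
#' @slot violations named list of character vectors, names A1..A6.
#' @slot allPass logical(1).
#' @exportClass PropertyReport
setClass("PropertyReport",
  representation(violations = "list", allPass = "logical")
)

setValidity("PropertyReport", function(object) {
  v <- object@violations
  if (!identical(names(v), paste0("A", 1:6))) {
    return("violations must be named A1..A6")
  }
  if (!identical(object@allPass, all(!lengths(v)))) {
    return("allPass inconsistent with violation lists")
  }
  TRUE
})

#' Arboreal network
#'
#' A multi-rooted DAG whose planted, undirected form is a phylogenetic tree:
#' every indegree->=2 vertex (reticulation) has outdegree one, every root
#' (indegree 0) has outdegree >= 2, no non-root vertex has total degree two,
#' and the outdegree-0 vertices are exactly the taxon-labelled leaves.
#'
#' @slot nVertex integer(1).
#' @slot arcs integer matrix, columns (tail, head).
#' @slot leafMap named integer vector, taxon to leaf vertex id.
#' @exportClass ArborealNetwork
setClass("ArborealNetwork",
  representation(nVertex = "integer", arcs = "matrix", leafMap = "integer")
)

setValidity("ArborealNetwork", function(object) {
  msg <- .arborealProblems(object)
  if (is.null(msg)) TRUE else msg
})

#' Planted arboreal network
#'
#' The planting of an arboreal network: one handle vertex r-hat with arc
#' (r-hat, r) per root r.  Handle names act as extra leaf labels of the
#' underlying tree and are disjoint from the network's taxa.
#'
#' @slot network the unplanted \linkS4class{ArborealNetwork}.
#' @slot nVertex,arcs,leafMap the planted graph, as in
#'   \linkS4class{ArborealNetwork}.
#' @slot handleMap named integer vector, handle name to handle vertex id
#'   (ids refer to the planted graph).
#' @exportClass PlantedNetwork
setClass("PlantedNetwork",
  representation(
    network = "ArborealNetwork",
    nVertex = "integer",
    arcs = "matrix",
    leafMap = "integer",
    handleMap = "integer"
  )
)

#' Core contraction of a binary augmented tree
#'
#' The contraction T^rho used by the orientation algorithm: subtrees holding
#' neither augmentation vertices nor root leaves are pruned (their edges
#' pre-directed towards the pruned leaves) and plain attachment vertices are
#' suppressed; \code{tau} records, per core edge, the vertex path it
#' replaces in the full tree.
#'
#' @slot core an \linkS4class{AugmentedTree} on the root handles and the
#'   leaves adjacent to augmentation vertices (may contain degree-2
#'   augmentation vertices).
#' @slot coreVertexOf integer vector mapping core vertex id to the vertex id
#'   in the input tree.
#' @slot tau list, one integer vector of input-tree vertex ids per core
#'   edge (path endpoints included).
#' @slot partial integer vector over input-tree edges: 0 unset, 1 directed
#'   from column-1 endpoint to column-2 endpoint, 2 the reverse.
#' @slot rho character(1), the chosen root handle.
#' @slot failed logical(1); TRUE when pruning already strands an
#'   augmentation vertex.
#' @slot failCode character(1) or NA.
#' @exportClass CoreContraction
setClass("CoreContraction",
  representation(
    core = "AugmentedTree",
    coreVertexOf = "integer",
    tau = "list",
    partial = "integer",
    rho = "character",
    failed = "logical",
    failCode = "character"
  )
)

#' Outcome of the orientation algorithm
#'
#' @slot success logical(1).
#' @slot network the oriented \linkS4class{ArborealNetwork} (SUCCESS only).
#' @slot code failure code (\code{"PRUNE_STRANDED_AUG"},
#'   \code{"VERTEX_INFEASIBLE"}, \code{"ENDGAME_CONFLICT"},
#'   \code{"POST_VALIDATION"}) or NA.
#' @slot witness integer vector of witness vertex ids (may be empty).
#' @exportClass OrientResult
setClass("OrientResult",
  representation(
    success = "logical",
    network = "ANY",
    code = "character",
    witness = "integer"
  )
)
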