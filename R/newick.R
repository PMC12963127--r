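## Newick boundary.  Parsing goes through ape; writing emits a canonical
## string directly (children ordered by smallest descendant taxon) so that
## output is bit-stable.  Branch lengths are neither read nor written.

.phyloToTree <- function(phy, mode = TREE_PHYLOGENETIC) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  edges <- phy$edge
  if (anyDuplicated(phy$tip.label)) stop("duplicate taxon in Newick input")
  lm <- structure(seq_len(ntip), names = phy$tip.label)
  tr <- .newUnrootedTree(n, edges, lm, mode = mode)
  validObject(tr)
  .assertNoLeafSubdivision(tr)
  tr
}

#' Read and write unrooted trees in Newick format
#'
#' \code{readNewick} parses a single Newick statement (unrooted convention:
#' the top-level vertex has at least three children unless the tree has at
#' most three leaves); \code{writeNewick} emits the canonical form, rooted
#' for writing at the interior vertex adjacent to the smallest taxon, with
#' children ordered by their smallest descendant taxon.
#'
#' @param text character(1), a Newick statement ending in ";".
#' @param mode tree mode; degree-two vertices are rejected in
#'   \code{"PHYLOGENETIC"} mode.
#' @return \code{readNewick}: an \linkS4class{UnrootedTree};
#'   \code{writeNewick}: character(1).
#' @examples
#' tr <- readNewick("((1,2),3,(4,5));")
#' writeNewick(tr)
#' @export
readNewick <- function(text, mode = TREE_PHYLOGENETIC) {
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) stop("Newick statement must end in ';'")
  if (grepl(";.*;", text)) stop("expected a single Newick statement")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) stop("malformed Newick: ", text)
  .phyloToTree(phy, mode = mode)
}

#' @rdname readNewick
#' @param tree an \linkS4class{UnrootedTree}.
#' @export
writeNewick <- function(tree) {
  stopifnot(is(tree, "UnrootedTree"))
  paste0(.newickString(tree, marks = NULL), ";")
}

## Shared canonical serializer.  `marks`: NULL or per-vertex character
## annotation appended to interior vertices (used for AUG labels).
## `arcTag`: NULL or function(parent, child) returning a per-edge prefix
## (used by network canonical forms).  Returns the unrooted string whose
## top level is the vertex adjacent to the smallest taxon.
.newickString <- function(tree, marks = NULL, arcTag = NULL) {
  taxa <- names(tree@leafMap)
  if (tree@nVertex == 1L) return(taxa[1L])
  adj <- .adjList(tree@nVertex, tree@edges)
  taxonOf <- .taxonOf(tree)
  smallest <- .sortTaxa(taxa)[1L]
  tip <- .leafVertex(tree, smallest)
  if (tree@nVertex == 2L) {
    other <- setdiff(taxa, smallest)
    return(paste0("(", smallest, ",", other, ")"))
  }
  root <- adj[[tip]][1L]
  serf <- function(v, parent) {
    kids <- setdiff(adj[[v]], parent)
    if (!length(kids)) return(list(str = taxonOf[v], min = taxonOf[v]))
    sub <- lapply(kids, serf, parent = v)
    mins <- vapply(sub, `[[`, character(1), "min")
    ord <- order(mins, method = "radix")
    strs <- vapply(sub[ord], `[[`, character(1), "str")
    if (!is.null(arcTag)) {
      tags <- vapply(kids[ord], function(k) arcTag(v, k), character(1))
      strs <- paste0(tags, strs)
    }
    lab <- if (!is.null(marks)) marks[v] else ""
    list(str = paste0("(", paste(strs, collapse = ","), ")", lab),
         min = mins[ord][1L])
  }
  serf(root, parent = 0L)$str
}

## Canonical string of a tree (optionally with marks / arc orientation
## annotations).  Two trees on the same taxa are equivalent (as leaf-
## labelled trees) iff their canonical strings agree, because a taxon-
## preserving isomorphism of trees is unique when it exists.
.canonicalString <- function(tree, marks = NULL, arcTag = NULL) {
  .newickString(tree, marks = marks, arcTag = arcTag)
}

#' Equivalence of leaf-labelled trees
#'
#' Two phylogenetic trees on the same taxa are equivalent when a graph
#' isomorphism between them fixes every taxon.  Tested via canonical forms.
#'
#' @param t1,t2 \linkS4class{UnrootedTree} objects.
#' @return logical(1); trees on different taxon sets compare FALSE.
#' @export
treesEquivalent <- function(t1, t2) {
  if (!setequal(names(t1@leafMap), names(t2@leafMap))) return(FALSE)
  identical(.canonicalString(t1), .canonicalString(t2))
}
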