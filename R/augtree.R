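## Augmented trees: construction, IO, equivalence, and the induced enhanced
## quartet tree system.

#' Construct an augmented tree
#'
#' Pairs an unrooted tree with a vertex marking.  Subdivision points
#' (degree-two vertices) are always augmentation points and are marked AUG
#' automatically; leaves may never be marked.
#'
#' @param tree an \linkS4class{UnrootedTree}.
#' @param aug which vertices are AUG: either a logical vector over all
#'   vertices or an integer vector of vertex ids.  Defaults to no marks
#'   beyond the automatic subdivision points.
#' @return an \linkS4class{AugmentedTree}.
#' @examples
#' tr <- readNewick("((1,2),3,(4,5));")
#' augmentedTree(tr, aug = treeMedian(tr, "1", "3", "4"))
#' @export
augmentedTree <- function(tree, aug = integer(0)) {
  stopifnot(is(tree, "UnrootedTree"))
  if (is.logical(aug)) {
    if (length(aug) != tree@nVertex) stop("logical aug must cover all vertices")
    a <- aug
  } else {
    a <- logical(tree@nVertex)
    a[as.integer(aug)] <- TRUE
  }
  a[.degrees(tree) == 2L] <- TRUE
  obj <- new("AugmentedTree", tree = tree, aug = a)
  validateAugmented(obj)
}

#' Validate an augmented tree
#'
#' Re-runs the class checks plus the structural rules a constructor
#' enforces: leaves unmarked, subdivision points marked AUG and never
#' adjacent to a leaf.
#'
#' @param x an \linkS4class{AugmentedTree}.
#' @return \code{x}, invisibly on the validation path; errors otherwise.
#' @export
validateAugmented <- function(x) {
  stopifnot(is(x, "AugmentedTree"))
  validObject(x)
  .assertNoLeafSubdivision(x@tree)
  x
}

#' Accessors for augmented trees
#'
#' \code{augVertices} returns the ids of the AUG-marked vertices;
#' \code{augTree} the underlying unrooted tree; \code{augMarks} the full
#' logical mark vector.
#'
#' @param x an \linkS4class{AugmentedTree}.
#' @return \code{augVertices}: integer vector; \code{augTree}:
#'   \linkS4class{UnrootedTree}; \code{augMarks}: logical vector.
#' @export
augVertices <- function(x) {
  stopifnot(is(x, "AugmentedTree"))
  which(x@aug)
}

#' @rdname augVertices
#' @export
augTree <- function(x) {
  stopifnot(is(x, "AugmentedTree"))
  x@tree
}

#' @rdname augVertices
#' @export
augMarks <- function(x) {
  stopifnot(is(x, "AugmentedTree"))
  x@aug
}

.augMarkStrings <- function(x) {
  ifelse(x@aug, "AUG", "")
}

#' Read and write augmented trees in annotated Newick
#'
#' The textual form is Newick with the internal-vertex label \code{AUG}
#' marking augmentation vertices; other internal labels are ignored with a
#' note.  Subdivision points appear as singly-nested parentheses.
#' \code{writeAugmentedNewick} emits the canonical form (see
#' \code{\link{writeNewick}}).
#'
#' @param text character(1), an annotated Newick statement.
#' @return \code{readAugmentedNewick}: an \linkS4class{AugmentedTree};
#'   \code{writeAugmentedNewick}: character(1).
#' @examples
#' at <- readAugmentedNewick("((1,2),3,(4,5)AUG);")
#' writeAugmentedNewick(at)
#' @export
readAugmentedNewick <- function(text) {
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) stop("Newick statement must end in ';'")
  if (grepl(";.*;", text)) stop("expected a single Newick statement")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) stop("malformed Newick: ", text)
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  deg <- tabulate(as.integer(phy$edge), nbins = n)
  mode <- if (any(deg == 2L)) TREE_PARTIALLY_SUBDIVIDED else TREE_PHYLOGENETIC
  tr <- .phyloToTree(phy, mode = mode)
  aug <- logical(n)
  labs <- phy$node.label
  if (!is.null(labs)) {
    labs[is.na(labs)] <- ""
    bad <- labs != "" & labs != "AUG"
    if (any(bad)) {
      message("ignoring internal label(s): ",
              paste(unique(labs[bad]), collapse = ", "))
    }
    aug[ntip + which(labs == "AUG")] <- TRUE
  }
  augmentedTree(tr, aug = aug)
}

#' @rdname readAugmentedNewick
#' @param x an \linkS4class{AugmentedTree}.
#' @export
writeAugmentedNewick <- function(x) {
  stopifnot(is(x, "AugmentedTree"))
  paste0(.newickString(x@tree, marks = .augMarkStrings(x)), ";")
}

#' Equivalence of augmented trees
#'
#' Two augmented trees are equivalent when a taxon-fixing tree isomorphism
#' carries one marking onto the other.  Tested via canonical annotated
#' Newick forms.
#'
#' @param x,y \linkS4class{AugmentedTree} objects.
#' @return logical(1); trees on different taxon sets compare FALSE.
#' @export
augmentationEquivalent <- function(x, y) {
  stopifnot(is(x, "AugmentedTree"), is(y, "AugmentedTree"))
  if (!setequal(names(x@tree@leafMap), names(y@tree@leafMap))) return(FALSE)
  identical(.canonicalString(x@tree, marks = .augMarkStrings(x)),
            .canonicalString(y@tree, marks = .augMarkStrings(y)))
}

#' Induced enhanced quartet tree system
#'
#' For each quartet tree ab|cd displayed by the augmented tree, records the
#' subdivision count gamma (the number of AUG vertices strictly between the
#' medians med(a,b,c) and med(c,d,a)) and the marks of those two medians.
#' Quartet trees not displayed are absent (gamma = -1 by convention).
#'
#' @param x an \linkS4class{AugmentedTree} with >= 4 leaves, phylogenetic
#'   (no subdivision points) and not a star tree.
#' @return an \linkS4class{EnhancedQuartetSystem}.
#' @examples
#' at <- readAugmentedNewick("((1,2),3,(4,5)AUG);")
#' gammaOf(inducedEQTS(at), quartet("1", "2", "4", "5"))
#' @export
inducedEQTS <- function(x) {
  stopifnot(is(x, "AugmentedTree"))
  tr <- x@tree
  if (tr@mode != TREE_PHYLOGENETIC) {
    stop("underlying tree must be phylogenetic (no subdivision points)")
  }
  if (length(tr@leafMap) < 4L) stop("need >= 4 leaves")
  qs <- displayedQuartets(tr)
  if (!length(qs)) stop("star tree displays no quartet")
  k <- length(qs)
  gam <- integer(k)
  nn <- character(k)
  nf <- character(k)
  for (i in seq_len(k)) {
    m <- .quartetMedianVertices(tr, qs[i])
    nn[i] <- if (x@aug[m[1L]]) MARK_AUG else MARK_PLAIN
    nf[i] <- if (x@aug[m[2L]]) MARK_AUG else MARK_PLAIN
    p <- .treePath(tr, m[1L], m[2L])
    inner <- p[-c(1L, length(p))]
    gam[i] <- sum(x@aug[inner])
  }
  enhancedQuartetSystem(names(tr@leafMap), qs, gam, nn, nf)
}
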