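## Enhanced quartet tree systems: construction, lookup, text IO.

#' Construct an enhanced quartet tree system
#'
#' @param ground character vector of taxa (>= 4).
#' @param quartets character vector of canonical quartet strings (see
#'   \code{\link{quartet}}); quartets on four taxa not listed here are
#'   absent from the system and have gamma -1.
#' @param gamma integer vector of subdivision counts (>= 0), aligned with
#'   \code{quartets}.
#' @param nuNear,nuFar character vectors of \code{"PLAIN"}/\code{"AUG"}:
#'   the marks of the pair-1-side and pair-2-side medians.
#' @return an \linkS4class{EnhancedQuartetSystem}; records are stored in
#'   sorted quartet order.
#' @export
enhancedQuartetSystem <- function(ground, quartets, gamma, nuNear, nuFar) {
  ord <- order(quartets, method = "radix")
  obj <- new("EnhancedQuartetSystem",
             ground = .sortTaxa(ground),
             quartets = quartets[ord],
             gamma = as.integer(gamma)[ord],
             nuNear = nuNear[ord],
             nuFar = nuFar[ord])
  validObject(obj)
  obj
}

## Hash from canonical quartet string to record index, for O(1) lookups.
.eqtsEnv <- function(sys) {
  e <- new.env(hash = TRUE, size = max(16L, 2L * length(sys@quartets)))
  q <- sys@quartets
  for (i in seq_along(q)) assign(q[i], i, envir = e)
  e
}

.eqtsIndex <- function(sys, key, env = NULL) {
  if (!is.null(env)) {
    i <- env[[key]]
    return(if (is.null(i)) 0L else i)
  }
  i <- match(key, sys@quartets)
  if (is.na(i)) 0L else i
}

#' Record lookup in an enhanced quartet tree system
#'
#' \code{gammaOf} returns the subdivision count of a quartet tree (-1 when
#' the quartet is absent).  \code{medianStatus} returns the stored mark of
#' the median determined by three of the quartet's taxa: for q = ab|cd the
#' triples containing both a and b name the pair-1-side median, those
#' containing both c and d the pair-2-side one.
#'
#' @param sys an \linkS4class{EnhancedQuartetSystem}.
#' @param key canonical quartet string.
#' @param triple character(3), three of the quartet's four taxa.
#' @return \code{gammaOf}: integer(1) >= -1; \code{medianStatus}:
#'   \code{"PLAIN"} or \code{"AUG"} (error if the quartet is absent).
#' @examples
#' at <- readAugmentedNewick("((1,2),3,(4,5)AUG);")
#' sys <- inducedEQTS(at)
#' gammaOf(sys, quartet("1", "2", "4", "5"))
#' medianStatus(sys, quartet("1", "3", "4", "5"), c("1", "3", "4"))
#' @export
gammaOf <- function(sys, key) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  i <- .eqtsIndex(sys, key)
  if (i == 0L) -1L else sys@gamma[i]
}

#' @rdname gammaOf
#' @export
medianStatus <- function(sys, key, triple) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  i <- .eqtsIndex(sys, key)
  if (i == 0L) stop("quartet absent from the system: ", key)
  .medianStatusAt(sys, i, key, triple)
}

.medianStatusAt <- function(sys, i, key, triple) {
  tx <- .quartetTaxa(key)
  if (length(triple) != 3L || anyDuplicated(triple) ||
      !all(triple %in% tx)) {
    stop("triple must be three distinct taxa of the quartet")
  }
  missing <- setdiff(tx, triple)
  ## missing taxon in pair 2 => the triple contains pair 1, naming the
  ## pair-1-side median
  if (missing %in% tx[3:4]) sys@nuNear[i] else sys@nuFar[i]
}

#' Taxa and support of a quartet system
#'
#' @param sys an \linkS4class{EnhancedQuartetSystem}.
#' @return \code{eqtsGround}: the taxon set; \code{eqtsQuartets}: the
#'   canonical strings of the supported quartet trees (sorted).
#' @export
eqtsGround <- function(sys) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  sys@ground
}

#' @rdname eqtsGround
#' @export
eqtsQuartets <- function(sys) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  sys@quartets
}

#' Equality of enhanced quartet tree systems
#'
#' Exact equality: same ground set, same supported quartets, and identical
#' gamma values and median marks record by record.
#'
#' @param a,b \linkS4class{EnhancedQuartetSystem} objects.
#' @return logical(1).
#' @export
eqtsEqual <- function(a, b) {
  stopifnot(is(a, "EnhancedQuartetSystem"), is(b, "EnhancedQuartetSystem"))
  identical(a@ground, b@ground) &&
    identical(a@quartets, b@quartets) &&
    identical(a@gamma, b@gamma) &&
    identical(a@nuNear, b@nuNear) &&
    identical(a@nuFar, b@nuFar)
}

#' Read and write quartet systems as TSV
#'
#' Plain-text format: a comment line \code{#EQTS v1}, optionally
#' \code{#X=<taxa, comma-separated>} naming the ground set (otherwise the
#' union of the row taxa is used), a header row, then one row per supported
#' quartet with columns \code{a b c d gamma nu_ab nu_cd} (a,b and c,d the
#' two pairs in canonical order; marks encoded 1 = AUG, 0 = PLAIN).
#'
#' @param path file path (or connection for \code{readEQTS}).
#' @return \code{readEQTS}: an \linkS4class{EnhancedQuartetSystem};
#'   \code{writeEQTS}: invisibly, \code{path}.
#' @export
readEQTS <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], "#EQTS")) {
    stop("not an EQTS file (missing '#EQTS' header)")
  }
  gline <- grep("^#X=", lines, value = TRUE)
  if (length(gline) > 1L) stop("expected at most one '#X=' line")
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2L) stop("no quartet rows")
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  want <- c("a", "b", "c", "d", "gamma", "nu_ab", "nu_cd")
  if (!identical(header, want)) {
    stop("bad column header; expected: ", paste(want, collapse = " "))
  }
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != 7L)) stop("malformed row (need 7 columns)")
  m <- do.call(rbind, rows)
  ground <- if (length(gline)) {
    strsplit(sub("^#X=", "", gline), ",", fixed = TRUE)[[1L]]
  } else unique(as.vector(m[, 1:4]))
  keys <- vapply(seq_len(nrow(m)), function(i)
    .quartetKey(m[i, 1L], m[i, 2L], m[i, 3L], m[i, 4L]), character(1))
  for (i in seq_len(nrow(m))) {
    if (!identical(keys[i], paste0(m[i, 1L], ",", m[i, 2L], "|",
                                   m[i, 3L], ",", m[i, 4L]))) {
      stop("row not in canonical pair order: ", paste(m[i, 1:4], collapse = " "))
    }
  }
  gam <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(gam)) stop("non-integer gamma value")
  if (any(gam < 0L)) stop("negative gamma value")
  if (!all(m[, 6:7] %in% c("0", "1"))) stop("marks must be 0 or 1")
  toMark <- function(v) ifelse(v == "1", MARK_AUG, MARK_PLAIN)
  enhancedQuartetSystem(ground, keys, gam, toMark(m[, 6L]), toMark(m[, 7L]))
}

#' @rdname readEQTS
#' @param sys an \linkS4class{EnhancedQuartetSystem}.
#' @export
writeEQTS <- function(sys, path) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  tx <- t(vapply(sys@quartets, .quartetTaxa, character(4)))
  rows <- paste(tx[, 1L], tx[, 2L], tx[, 3L], tx[, 4L], sys@gamma,
                as.integer(sys@nuNear == MARK_AUG),
                as.integer(sys@nuFar == MARK_AUG), sep = "\t")
  writeLines(c("#EQTS v1",
               paste0("#X=", paste(sys@ground, collapse = ",")),
               paste(c("a", "b", "c", "d", "gamma", "nu_ab", "nu_cd"),
                     collapse = "\t"),
               rows), path)
  invisible(path)
}
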