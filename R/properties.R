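## The six characteristic properties of enhanced quartet tree systems, and
## the supported-augmentation-point test underlying the fourth one.

#' Support test for an augmentation point
#'
#' A quartet record q = ab|cd with subdivision count gamma(q) >= 1 stands
#' for a quartet tree whose middle path carries gamma(q) augmentation
#' points.  Point i (counted from the ab-side median) is supported when
#' some outside taxon z pins it down: for one of the symmetric writings of
#' q there are records q'' = ab|dz with gamma i-1 and q' = bz|cd with gamma
#' gamma(q)-i, and in both the median of \{b,d,z\} is marked AUG (that
#' median is where z attaches, i.e. the point itself).  Writing q with the
#' pairs swapped mirrors the index to gamma(q)+1-i.
#'
#' @param sys an \linkS4class{EnhancedQuartetSystem}.
#' @param key canonical quartet string, present in \code{sys}.
#' @param i integer position, 1 <= i <= gamma(key).
#' @return logical(1); when TRUE, carries an attribute \code{witness}, a
#'   named character vector with the outside taxon \code{z} and the two
#'   supporting quartets \code{qPrime} (bz|cd-shaped) and
#'   \code{qDoublePrime} (ab|dz-shaped).
#' @export
isSupported <- function(sys, key, i) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  env <- .eqtsEnv(sys)
  g <- gammaOf(sys, key)
  if (g < 0L) stop("quartet absent from the system: ", key)
  if (i < 1L || i > g) stop("point index out of range")
  .isSupportedAt(sys, key, as.integer(i), g, env)
}

.isSupportedAt <- function(sys, key, i, g, env) {
  tx <- .quartetTaxa(key)
  a <- tx[1L]; b <- tx[2L]; c <- tx[3L]; d <- tx[4L]
  ## labellings (A,B,C,D, index): swapping within a pair keeps the index;
  ## swapping the pairs reverses the path, mirroring the index
  labs <- list(
    list(a, b, c, d, i), list(b, a, c, d, i),
    list(a, b, d, c, i), list(b, a, d, c, i),
    list(c, d, a, b, g + 1L - i), list(d, c, a, b, g + 1L - i),
    list(c, d, b, a, g + 1L - i), list(d, c, b, a, g + 1L - i)
  )
  outside <- setdiff(sys@ground, tx)
  for (L in labs) {
    A <- L[[1L]]; B <- L[[2L]]; C <- L[[3L]]; D <- L[[4L]]; ii <- L[[5L]]
    for (z in outside) {
      k2 <- .quartetKey(A, B, D, z)          # q'' = AB|Dz
      j2 <- .eqtsIndex(sys, k2, env)
      if (j2 == 0L || sys@gamma[j2] != ii - 1L) next
      k1 <- .quartetKey(B, z, C, D)          # q' = Bz|CD
      j1 <- .eqtsIndex(sys, k1, env)
      if (j1 == 0L || sys@gamma[j1] != g - ii) next
      tri <- c(B, D, z)
      if (.medianStatusAt(sys, j2, k2, tri) != MARK_AUG) next
      if (.medianStatusAt(sys, j1, k1, tri) != MARK_AUG) next
      out <- TRUE
      attr(out, "witness") <- c(z = z, qPrime = k1, qDoublePrime = k2)
      return(out)
    }
  }
  FALSE
}

#' Verify the six characteristic properties of a quartet system
#'
#' Checks the conditions characterizing the quartet systems induced by
#' augmented trees: (A1) at most one topology per four-taxon set; (A2)
#' every supported quartet extends consistently past any fifth taxon; (A3)
#' records sharing three taxa agree on the shared median's mark; (A4) every
#' augmentation point is supported (\code{\link{isSupported}}); (A5)/(A6)
#' the subdivision counts add up along overlapping quartets, with the
#' shared median's mark contributing one when AUG.
#'
#' @param sys an \linkS4class{EnhancedQuartetSystem}.
#' @return a \linkS4class{PropertyReport}; inspect \code{reportViolations}
#'   and \code{reportPasses}.
#' @export
checkProperties <- function(sys) {
  stopifnot(is(sys, "EnhancedQuartetSystem"))
  env <- .eqtsEnv(sys)
  q <- sys@quartets
  k <- length(q)
  txs <- lapply(q, .quartetTaxa)
  sets <- vapply(txs, function(t) paste(.sortTaxa(t), collapse = ","),
                 character(1))
  viol <- list(A1 = character(0), A2 = character(0), A3 = character(0),
               A4 = character(0), A5 = character(0), A6 = character(0))

  ## A1: one topology per 4-set
  dup <- split(q, sets)
  for (grp in dup) {
    if (length(grp) > 1L) {
      viol$A1 <- c(viol$A1, paste("conflicting topologies:",
                                  paste(grp, collapse = " vs ")))
    }
  }

  gOf <- function(a, b, c, d) {
    j <- .eqtsIndex(sys, .quartetKey(a, b, c, d), env)
    if (j == 0L) -1L else sys@gamma[j]
  }

  ## A2: extension past any fifth taxon
  for (idx in seq_len(k)) {
    tx <- txs[[idx]]
    a <- tx[1L]; b <- tx[2L]; c <- tx[3L]; d <- tx[4L]
    for (x in setdiff(sys@ground, tx)) {
      ok <- (gOf(a, b, c, x) >= 0L && gOf(a, b, d, x) >= 0L) ||
        (gOf(a, x, c, d) >= 0L && gOf(b, x, c, d) >= 0L)
      if (!ok) {
        viol$A2 <- c(viol$A2, paste0(q[idx], " does not extend past ", x))
      }
    }
  }

  ## A3: shared-triple median marks agree.  Each record fixes the mark of
  ## the median of each of its four taxon triples.
  seen <- new.env(hash = TRUE)
  for (idx in seq_len(k)) {
    tx <- txs[[idx]]
    for (drop in 1:4) {
      tri <- tx[-drop]
      triKey <- paste(.sortTaxa(tri), collapse = ",")
      mark <- .medianStatusAt(sys, idx, q[idx], tri)
      prev <- seen[[triKey]]
      if (is.null(prev)) {
        seen[[triKey]] <- c(mark, q[idx])
      } else if (prev[1L] != mark) {
        viol$A3 <- c(viol$A3, paste0("median of {", triKey, "} marked ",
                                     prev[1L], " in ", prev[2L], " but ",
                                     mark, " in ", q[idx]))
      }
    }
  }

  ## A4: every augmentation point supported
  for (idx in seq_len(k)) {
    g <- sys@gamma[idx]
    for (i in seq_len(g)) {
      if (!isTRUE(.isSupportedAt(sys, q[idx], i, g, env))) {
        viol$A4 <- c(viol$A4, paste0("point ", i, " of ", q[idx],
                                     " unsupported"))
      }
    }
  }

  ## A5/A6: enumerate ordered record pairs and match the label patterns.
  ## Both patterns require the two records to share exactly three taxa, and
  ## such records share exactly one taxon triple, so grouping the records
  ## by triple visits every relevant pair (pairs sharing a full 4-set occur
  ## in several groups but match neither pattern).
  byTriple <- new.env(hash = TRUE)
  for (idx in seq_len(k)) {
    tx <- txs[[idx]]
    for (drop in 1:4) {
      triKey <- paste(.sortTaxa(tx[-drop]), collapse = ",")
      byTriple[[triKey]] <- c(byTriple[[triKey]], idx)
    }
  }
  pairGroups <- as.list(byTriple)
  for (grp in pairGroups) {
  if (length(grp) < 2L) next
  for (i1 in grp) {
    tx1 <- txs[[i1]]
    p1a <- tx1[1:2]; p1b <- tx1[3:4]
    for (i2 in grp) {
      if (i2 == i1) next
      tx2 <- txs[[i2]]
      p2a <- tx2[1:2]; p2b <- tx2[3:4]

      ## --- A5 pattern: q1 = ab|cd, q2 = ab|ce with gamma(q1) > gamma(q2)
      if (sys@gamma[i1] > sys@gamma[i2]) {
        for (pr1 in list(list(p1a, p1b), list(p1b, p1a))) {
          for (pr2 in list(list(p2a, p2b), list(p2b, p2a))) {
            if (!setequal(pr1[[1L]], pr2[[1L]])) next
            cc <- intersect(pr1[[2L]], pr2[[2L]])
            if (length(cc) != 1L) next
            d <- setdiff(pr1[[2L]], cc)
            e <- setdiff(pr2[[2L]], cc)
            mark <- .medianStatusAt(sys, i2, q[i2],
                                    c(pr2[[1L]][1L], cc, e))
            bump <- if (mark == MARK_AUG) 1L else 0L
            want <- sys@gamma[i1] - sys@gamma[i2] - bump
            for (ab in list(pr1[[1L]], rev(pr1[[1L]]))) {
              gotten <- gOf(ab[1L], e, cc, d)
              if (gotten != want) {
                viol$A5 <- c(viol$A5, paste0(
                  "gamma(", .quartetKey(ab[1L], e, cc, d), ") = ", gotten,
                  " but ", q[i1], ", ", q[i2], " require ", want))
              }
            }
          }
        }
      }

      ## --- A6 pattern: q1 = ab|cd, q2 = bc|de
      a <- setdiff(tx1, tx2)
      e <- setdiff(tx2, tx1)
      if (length(a) == 1L && length(e) == 1L) {
        ## b = partner of a in q1; then {c,d} is q1's other pair
        pairOfA <- if (a %in% p1a) p1a else p1b
        other1 <- if (a %in% p1a) p1b else p1a
        b <- setdiff(pairOfA, a)
        pairOfE <- if (e %in% p2a) p2a else p2b
        other2 <- if (e %in% p2a) p2b else p2a
        d <- setdiff(pairOfE, e)
        if (setequal(other2, c(b, setdiff(other1, d))) && d %in% other1) {
          cc <- setdiff(other1, d)
          mark <- .medianStatusAt(sys, i1, q[i1], c(b, cc, d))
          bump <- if (mark == MARK_AUG) 1L else 0L
          want <- sys@gamma[i1] + sys@gamma[i2] + bump
          gotten <- gOf(a, b, d, e)
          if (gotten != want) {
            viol$A6 <- c(viol$A6, paste0(
              "gamma(", .quartetKey(a, b, d, e), ") = ", gotten,
              " but ", q[i1], ", ", q[i2], " require ", want))
          }
        }
      }
    }
  }
  }

  viol <- lapply(viol, unique)
  new("PropertyReport", violations = viol, allPass = all(!lengths(viol)))
}

#' Inspect a property report
#'
#' @param report a \linkS4class{PropertyReport}.
#' @param property optional property name \code{"A1"}..\code{"A6"}.
#' @return \code{reportViolations}: the named list of violation messages
#'   (or one element's messages); \code{reportPasses}: logical(1).
#' @export
reportViolations <- function(report, property = NULL) {
  stopifnot(is(report, "PropertyReport"))
  if (is.null(property)) report@violations else report@violations[[property]]
}

#' @rdname reportViolations
#' @export
reportPasses <- function(report) {
  stopifnot(is(report, "PropertyReport"))
  report@allPass
}
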