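## Compact show() methods for every exported class.

setMethod("show", "UnrootedTree", function(object) {
  cat("UnrootedTree:", length(object@leafMap), "leaves,",
      object@nVertex, "vertices (", object@mode, ")\n", sep = " ")
  cat(" ", writeNewick(object), "\n")
})

setMethod("show", "SplitSystem", function(object) {
  cat("SplitSystem on", length(object@ground), "taxa:",
      length(object@splits), "split(s)\n")
  for (s in utils::head(object@splits, 8L)) cat("  ", s, "\n")
  if (length(object@splits) > 8L) {
    cat("  ... and", length(object@splits) - 8L, "more\n")
  }
})

setMethod("show", "AugmentedTree", function(object) {
  cat("AugmentedTree:", length(object@tree@leafMap), "leaves,",
      sum(object@aug), "augmentation vertex(es)\n")
  cat(" ", writeAugmentedNewick(object), "\n")
})

setMethod("show", "EnhancedQuartetSystem", function(object) {
  cat("EnhancedQuartetSystem on {",
      paste(object@ground, collapse = ", "), "}: ",
      length(object@quartets), " quartet record(s)\n", sep = "")
  k <- min(length(object@quartets), 6L)
  for (i in seq_len(k)) {
    cat(sprintf("  %-14s gamma=%d  nu=%s/%s\n", object@quartets[i],
                object@gamma[i], object@nuNear[i], object@nuFar[i]))
  }
  if (length(object@quartets) > k) {
    cat("  ... and", length(object@quartets) - k, "more\n")
  }
})

setMethod("show", "PropertyReport", function(object) {
  if (object@allPass) {
    cat("PropertyReport: all six properties hold\n")
  } else {
    bad <- names(which(lengths(object@violations) > 0L))
    cat("PropertyReport: violations of", paste(bad, collapse = ", "), "\n")
    for (p in bad) {
      for (m in utils::head(object@violations[[p]], 3L)) {
        cat("  [", p, "] ", m, "\n", sep = "")
      }
      extra <- length(object@violations[[p]]) - 3L
      if (extra > 0L) cat("  [", p, "] ... and ", extra, " more\n", sep = "")
    }
  }
})

setMethod("show", "ArborealNetwork", function(object) {
  d <- .arcDegrees(object@nVertex, object@arcs)
  cat("ArborealNetwork:", length(object@leafMap), "leaves,",
      object@nVertex, "vertices,", nrow(object@arcs), "arcs;",
      sum(d$indeg == 0L), "root(s),", sum(d$indeg >= 2L),
      "reticulation(s)\n")
})

setMethod("show", "PlantedNetwork", function(object) {
  cat("PlantedNetwork:", length(object@handleMap), "handle(s) [",
      paste(names(object@handleMap), collapse = ", "), "] over\n")
  show(object@network)
})

setMethod("show", "CoreContraction", function(object) {
  if (object@failed) {
    cat("CoreContraction: FAILED (", object@failCode, ")\n", sep = "")
  } else {
    cat("CoreContraction (rho = ", object@rho, "): core with ",
        object@core@tree@nVertex, " vertices, ",
        sum(object@partial != 0L), "/", length(object@partial),
        " edges pre-directed\n", sep = "")
  }
})

setMethod("show", "OrientResult", function(object) {
  if (object@success) {
    cat("OrientResult: SUCCESS\n")
    show(object@network)
  } else {
    cat("OrientResult: FAILURE (", object@code, ")",
        if (length(object@witness)) {
          paste0("; witness vertices: ",
                 paste(object@witness, collapse = ", "))
        } else "", "\n", sep = "")
  }
})
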