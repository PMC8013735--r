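#' @rdname TimeCourseSet-class
#' @export
setMethod("nSubjects", "TimeCourseSet", function(x) length(x@signals))

#' @rdname TimeCourseSet-class
#' @export
setMethod("subjectInfo", "TimeCourseSet", function(x) x@subjects)

#' @rdname TimeCourseSet-class
#' @export
setMethod("signals", "TimeCourseSet", function(x) x@signals)

#' @rdname TimeCourseSet-class
#' @export
setMethod("nodeNames", "TimeCourseSet", function(x) x@nodeNames)

#' @rdname DFCSet-class
#' @export
setMethod("nodeNames", "DFCSet", function(x) x@nodeNames)

#' @rdname TimeCourseSet-class
#' @export
setMethod("trSeconds", "TimeCourseSet", function(x) x@trSeconds)

#' @rdname TaperSpec-class
#' @export
setMethod("trSeconds", "TaperSpec", function(x) x@trSeconds)

#' @rdname TaperSpec-class
#' @export
setMethod("taperWeights", "TaperSpec", function(x) x@weights)

#' @rdname StateModel-class
#' @export
setMethod("nStates", "StateModel", function(x) x@nStates)

#' @rdname TransitionSet-class
#' @export
setMethod("nStates", "TransitionSet", function(x) x@nStates)

#' @rdname CohortConfig-class
#' @param x a `CohortConfig`.
#' @export
setMethod("nStates", "CohortConfig", function(x) x@nStates)

#' @rdname StateModel-class
#' @export
setMethod("centroids", "StateModel", function(x) x@centroids)

#' @rdname StateModel-class
#' @export
setMethod("stateSequences", "StateModel", function(x) x@assignments)

#' @rdname DFCSet-class
#' @export
setMethod("featureIndex", "DFCSet", function(x) x@featureIndex)

#' @rdname TransitionSet-class
#' @export
setMethod("featureMatrix", "TransitionSet", function(x) x@featureMatrix)

#' @rdname TransitionSet-class
#' @export
setMethod("transitionMatrices", "TransitionSet", function(x) x@matrices)

#' @rdname TimeCourseSet-class
#' @export
setMethod("nSubjects", "DFCSet", function(x) length(x@features))

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nHC, "HC +", object@nSZ, "SZ subjects,",
      object@nNodes, "nodes,", object@nStates, "states,",
      object@nTimepoints, "timepoints (TR", object@trSeconds, "s)\n")
  lk <- object@symptomLink
  cat(sprintf("  planted symptom link: P(%d->%d) ~ %s, target r = %.2f\n",
              lk$from, lk$to, lk$scale, lk$targetR))
})

setMethod("show", "TimeCourseSet", function(object) {
  tab <- table(object@subjects$group)
  cat("TimeCourseSet:", nSubjects(object), "subjects (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      length(object@nodeNames), "nodes, TR", object@trSeconds, "s\n")
  if (nSubjects(object) > 0)
    cat("  timepoints:", nrow(object@signals[[1]]), "; nodes:",
        paste(object@nodeNames, collapse = ", "), "\n")
  if (length(object@truth)) cat("  synthetic: generator ground truth attached\n")
})

setMethod("show", "TaperSpec", function(object) {
  cat(sprintf("TaperSpec: L = %d TRs (%.0f s at TR = %g s), sigma = %g s, %d weights\n",
              object@windowTRs, object@windowTRs * object@trSeconds,
              object@trSeconds, object@sigmaSeconds, length(object@weights)))
})

setMethod("show", "DFCSet", function(object) {
  Ts <- vapply(object@features, nrow, integer(1))
  cat("DFCSet:", length(object@features), "subjects,",
      nrow(object@featureIndex), "node-pair features,",
      if (length(unique(Ts)) == 1) paste(Ts[1], "windows each") else
        paste("windows", paste(range(Ts), collapse = "-")),
      sprintf("(windowed %s)\n", object@stat))
})

setMethod("show", "StateModel", function(object) {
  cat("StateModel:", object@nStates, "states over",
      length(object@assignments), "subjects (distance:", object@distance, ")\n")
  if (nrow(object@inertiaCurve))
    cat(sprintf("  elbow-selected K (knee strength %.3f) over k = %s\n",
                object@kneeStrength,
                paste(range(object@inertiaCurve$k), collapse = "..")))
})

setMethod("show", "TransitionSet", function(object) {
  cat("TransitionSet:", length(object@matrices), "subjects,",
      object@nStates^2, "transition features (K =", object@nStates, ")\n")
  flagged <- sum(is.na(object@featureMatrix))
  if (flagged) cat("  ", flagged, "entries flagged NA (origin state unvisited)\n")
})
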