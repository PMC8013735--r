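#' @rdname TimeCourseSet-class
#' @param x,object an object.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname TimeCourseSet-class
#' @export
setGeneric("subjectInfo", function(x) standardGeneric("subjectInfo"))

#' @rdname TimeCourseSet-class
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname TimeCourseSet-class
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname TimeCourseSet-class
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname TaperSpec-class
#' @param x an object.
#' @export
setGeneric("taperWeights", function(x) standardGeneric("taperWeights"))

#' @rdname StateModel-class
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname StateModel-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname StateModel-class
#' @export
setGeneric("stateSequences", function(x) standardGeneric("stateSequences"))

#' @rdname DFCSet-class
#' @export
setGeneric("featureIndex", function(x) standardGeneric("featureIndex"))

#' @rdname TransitionSet-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname TransitionSet-class
#' @export
setGeneric("transitionMatrices", function(x) standardGeneric("transitionMatrices"))
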