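#' @rdname ScaClassification-class
#' @param x,object an object.
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname ScaClassification-class
#' @export
setGeneric("subjectResults", function(x) standardGeneric("subjectResults"))

#' @rdname ScaClassification-class
#' @export
setGeneric("scaLabels", function(x) standardGeneric("scaLabels"))

#' @rdname ScaClassification-class
#' @export
setGeneric("genericModel", function(x) standardGeneric("genericModel"))

#' @rdname TestBattery-class
#' @export
setGeneric("batteryTests", function(x) standardGeneric("batteryTests"))

#' @rdname TestBattery-class
#' @export
setGeneric("specificTests", function(x) standardGeneric("specificTests"))

#' @rdname SubjectCohort-class
#' @export
setGeneric("cognitiveScores", function(x, ...) standardGeneric("cognitiveScores"))

#' @rdname SubjectCohort-class
#' @export
setGeneric("idpMatrix", function(x) standardGeneric("idpMatrix"))

#' @rdname SubjectCohort-class
#' @export
setGeneric("demographics", function(x) standardGeneric("demographics"))

#' @rdname ConfoundFit-class
#' @export
setGeneric("residualMatrix", function(x) standardGeneric("residualMatrix"))

#' @rdname ConfoundFit-class
#' @export
setGeneric("confoundCoefficients", function(x) standardGeneric("confoundCoefficients"))
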