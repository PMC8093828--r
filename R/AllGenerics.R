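#' @rdname AsvExperiment
#' @param x an object.
#' @export
setGeneric("asvCounts", function(x) standardGeneric("asvCounts"))

#' @rdname AsvExperiment
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname AsvExperiment
#' @export
setGeneric("sampleDepths", function(x) standardGeneric("sampleDepths"))

#' @rdname RelAbundanceExperiment-class
#' @param x an object.
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname DepthLadder-class
#' @param x an object.
#' @export
setGeneric("ladderLevels", function(x) standardGeneric("ladderLevels"))

#' @rdname ModelGridResult-class
#' @param x an object.
#' @export
setGeneric("gridRecords", function(x) standardGeneric("gridRecords"))

#' @rdname ModelGridResult-class
#' @export
setGeneric("medianKappa", function(x) standardGeneric("medianKappa"))

#' @rdname ModelGridResult-class
#' @export
setGeneric("meanOobError", function(x) standardGeneric("meanOobError"))

#' @rdname ModelGridResult-class
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @rdname DepthDecision-class
#' @param x an object.
#' @export
setGeneric("minDepth", function(x) standardGeneric("minDepth"))

#' @rdname DepthDecision-class
#' @export
setGeneric("levelSummary", function(x) standardGeneric("levelSummary"))

#' @rdname SeparabilityReport-class
#' @param x an object.
#' @export
setGeneric("ellipseOverlap", function(x) standardGeneric("ellipseOverlap"))

#' @rdname SeparabilityReport-class
#' @export
setGeneric("featureCvValues", function(x) standardGeneric("featureCvValues"))
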