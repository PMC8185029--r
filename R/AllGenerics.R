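#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("keptMask", function(x) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureIndex", function(x) standardGeneric("featureIndex"))

#' @rdname accessors
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("baselinePower", function(x) standardGeneric("baselinePower"))

#' @rdname accessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname accessors
#' @export
setGeneric("balancedAccuracies", function(x) standardGeneric("balancedAccuracies"))

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname accessors
#' @export
setGeneric("maxAccuracy", function(x) standardGeneric("maxAccuracy"))

#' @rdname accessors
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
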