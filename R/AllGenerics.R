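#' @rdname featureValues
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname subjectIds
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname classLabels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname samplingRate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname channelNames
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ncaWeights
#' @export
setGeneric("ncaWeights", function(object) standardGeneric("ncaWeights"))

#' @rdname selectedFeatures
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname gfkKernel
#' @export
setGeneric("gfkKernel", function(object) standardGeneric("gfkKernel"))

#' @rdname accuracies
#' @export
setGeneric("accuracies", function(object) standardGeneric("accuracies"))
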