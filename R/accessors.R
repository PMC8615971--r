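#' Feature matrix in instances x features orientation
#'
#' @param x an [EEGFeatureSet-class].
#' @return numeric matrix, rows = instances, columns = named features.
#' @export
#' @rdname featureValues
setMethod("featureValues", "EEGFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' Per-instance subject identifiers
#'
#' @param x an [EEGFeatureSet-class], [EEGRecordingSet-class] or
#'   [EEGSegmentSet-class].
#' @return character vector.
#' @export
#' @rdname subjectIds
setMethod("subjectIds", "EEGFeatureSet", function(x) {
  as.character(SummarizedExperiment::colData(x)$subject_id)
})

#' @export
#' @rdname subjectIds
setMethod("subjectIds", "EEGRecordingSet", function(x) {
  as.character(x@trialInfo$subject_id)
})

#' @export
#' @rdname subjectIds
setMethod("subjectIds", "EEGSegmentSet", function(x) {
  as.character(x@segmentInfo$subject_id)
})

#' Per-instance three-class labels (0 = low, 1 = neutral, 2 = high)
#'
#' @param x an [EEGFeatureSet-class], [EEGRecordingSet-class] or
#'   [EEGSegmentSet-class].
#' @return integer vector of class indices.
#' @export
#' @rdname classLabels
setMethod("classLabels", "EEGFeatureSet", function(x) {
  as.integer(SummarizedExperiment::colData(x)$label)
})

#' @export
#' @rdname classLabels
setMethod("classLabels", "EEGRecordingSet", function(x) {
  as.integer(x@trialInfo$label)
})

#' @export
#' @rdname classLabels
setMethod("classLabels", "EEGSegmentSet", function(x) {
  as.integer(x@segmentInfo$label)
})

#' Sampling rate in Hz
#' @param x an [EEGRecordingSet-class] or [EEGSegmentSet-class].
#' @return numeric(1), Hz.
#' @export
#' @rdname samplingRate
setMethod("samplingRate", "EEGRecordingSet", function(x) x@fs)

#' @export
#' @rdname samplingRate
setMethod("samplingRate", "EEGSegmentSet", function(x) x@fs)

#' Electrode names of the montage
#' @param x an [EEGRecordingSet-class] or [EEGSegmentSet-class].
#' @return character vector.
#' @export
#' @rdname channelNames
setMethod("channelNames", "EEGRecordingSet", function(x) x@channelNames)

#' @export
#' @rdname channelNames
setMethod("channelNames", "EEGSegmentSet", function(x) x@channelNames)

#' Learned NCA feature weights
#' @param object an [NCAModel-class].
#' @return named numeric vector of weight magnitudes.
#' @export
#' @rdname ncaWeights
setMethod("ncaWeights", "NCAModel", function(object) {
  w <- object@w
  if (length(object@featureNames)) names(w) <- object@featureNames
  w
})

#' Logical mask of NCA-selected features
#' @param object an [NCAModel-class].
#' @return logical vector.
#' @export
#' @rdname selectedFeatures
setMethod("selectedFeatures", "NCAModel", function(object) object@selectedMask)

#' Geodesic flow kernel matrix
#' @param object a [GFKModel-class].
#' @return symmetric D x D matrix.
#' @export
#' @rdname gfkKernel
setMethod("gfkKernel", "GFKModel", function(object) object@G)

#' Per-held-out-subject accuracies
#' @param object a [LOSOReport-class] or [DFSResult-class].
#' @return named numeric vector.
#' @export
#' @rdname accuracies
setMethod("accuracies", "LOSOReport", function(object) object@accuracies)

#' @export
#' @rdname accuracies
setMethod("accuracies", "DFSResult", function(object) {
  a <- object@accuracies
  names(a) <- object@subjects
  a
})

setMethod("show", "EEGRecordingSet", function(object) {
  cat(sprintf(
    "EEGRecordingSet: %d subjects, %d trials, %d channels @ %g Hz\n",
    length(object@signals), nrow(object@trialInfo),
    length(object@channelNames), object@fs))
  tab <- table(factor(object@trialInfo$label, levels = 0:2))
  cat(sprintf("  class counts (low/neutral/high): %s\n",
              paste(tab, collapse = "/")))
})

setMethod("show", "EEGSegmentSet", function(object) {
  len <- if (length(object@segments)) ncol(object@segments[[1]]) else 0L
  cat(sprintf(
    "EEGSegmentSet: %d segments of %d samples, %d channels @ %g Hz\n",
    length(object@segments), len, length(object@channelNames), object@fs))
})

setMethod("show", "NCAModel", function(object) {
  cat(sprintf(
    "NCAModel: %d features, lambda = %g, sigma = %g\n",
    length(object@w), object@lambda, object@sigma))
  if (length(object@objectiveTrace))
    cat(sprintf("  objective: %.6f -> %.6f (%d iterations)\n",
                object@objectiveTrace[1],
                object@objectiveTrace[length(object@objectiveTrace)],
                length(object@objectiveTrace) - 1L))
  if (length(object@selectedMask))
    cat(sprintf("  selected features: %d\n", sum(object@selectedMask)))
})

setMethod("show", "GFKModel", function(object) {
  cat(sprintf("GFKModel: D = %d, d* = %d\n", nrow(object@G), object@dStar))
  cat(sprintf("  principal angles (deg): %s\n",
              paste(sprintf("%.2f", object@principalAngles * 180 / pi),
                    collapse = ", ")))
})

setMethod("show", "DFSResult", function(object) {
  cat(sprintf("DFSResult: %d folds, mean accuracy %.4f\n",
              length(object@subjects),
              mean(object@accuracies, na.rm = TRUE)))
})

setMethod("show", "LOSOReport", function(object) {
  cat(sprintf("LOSOReport [%s / %s]: %d subjects, accuracy %.4f (sd %.4f)\n",
              object@pipeline, object@classifier,
              length(object@accuracies),
              object@meanAccuracy, object@sdAccuracy))
})
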