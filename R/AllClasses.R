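#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Multi-subject EEG recordings with trial metadata
#'
#' Container for raw or preprocessed multi-subject EEG. Each subject holds a
#' list of trials, each trial a channels x samples matrix in microvolts.
#' Per-trial affective ratings (1-9 scale) and/or three-class labels
#' (0 = low, 1 = neutral, 2 = high) are kept in `trialInfo`.
#'
#' @slot signals list; one element per subject, each a list of
#'   channels x samples numeric matrices.
#' @slot fs numeric(1); sampling rate in Hz.
#' @slot channelNames character; ordered electrode names (10-20 montage).
#' @slot trialInfo data.frame with columns `subject_id`, `trial`, `rating`
#'   (NA when labels are categorical) and `label` (integer 0/1/2).
#'
#' @export
setClass("EEGRecordingSet",
  representation(
    signals = "list",
    fs = "numeric",
    channelNames = "character",
    trialInfo = "data.frame"
  )
)

setValidity("EEGRecordingSet", function(object) {
  msg <- character()
  nch <- length(object@channelNames)
  for (s in seq_along(object@signals)) {
    trials <- object@signals[[s]]
    if (!all(vapply(trials, is.matrix, logical(1))))
      msg <- c(msg, sprintf("subject %d: all trials must be matrices", s))
    else if (!all(vapply(trials, nrow, integer(1)) == nch))
      msg <- c(msg, sprintf("subject %d: channel count differs from montage", s))
  }
  ntr <- sum(lengths(object@signals))
  if (nrow(object@trialInfo) != ntr)
    msg <- c(msg, "trialInfo rows must match total trial count")
  r <- object@trialInfo$rating
  if (any(!is.na(r) & (r < 1 | r > 9)))
    msg <- c(msg, "ratings must lie in [1, 9]")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Non-overlapping equal-length EEG segments with inherited labels
#'
#' @slot segments list of channels x samples matrices.
#' @slot fs numeric(1) sampling rate in Hz.
#' @slot channelNames character, electrode names.
#' @slot segmentInfo data.frame with columns `subject_id`, `trial`,
#'   `segment`, `label`.
#'
#' @export
setClass("EEGSegmentSet",
  representation(
    segments = "list",
    fs = "numeric",
    channelNames = "character",
    segmentInfo = "data.frame"
  )
)

setValidity("EEGSegmentSet", function(object) {
  msg <- character()
  if (length(object@segments) != nrow(object@segmentInfo))
    msg <- c(msg, "segmentInfo rows must match number of segments")
  if (length(object@segments)) {
    lens <- vapply(object@segments, ncol, integer(1))
    if (length(unique(lens)) != 1L)
      msg <- c(msg, "all segments must have equal length")
    if (!all(vapply(object@segments, nrow, integer(1)) ==
             length(object@channelNames)))
      msg <- c(msg, "segment channel count differs from montage")
  }
  if (length(msg)) msg else TRUE
})

#' Instances-by-features matrix with subject IDs and class labels
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] storing
#' the feature matrix as a features x instances assay named `"features"`,
#' with `subject_id` and `label` in `colData`. Use [featureValues()] to get
#' the conventional instances x features orientation.
#'
#' @export
setClass("EEGFeatureSet", contains = "SummarizedExperiment")

#' Neighborhood component analysis model
#'
#' @slot w numeric; learned per-feature weights (reported as magnitudes;
#'   entering the metric squared).
#' @slot lambda numeric(1); L2 regularization strength.
#' @slot sigma numeric(1); kernel width of the stochastic 1-NN rule.
#' @slot objectiveTrace numeric; objective value per accepted iteration.
#' @slot selectedMask logical; feature selection mask (see [selectFeatures()]).
#' @slot featureNames character.
#'
#' @export
setClass("NCAModel",
  representation(
    w = "numeric",
    lambda = "numeric",
    sigma = "numeric",
    objectiveTrace = "numeric",
    selectedMask = "logical",
    featureNames = "character"
  )
)

setValidity("NCAModel", function(object) {
  msg <- character()
  if (length(object@selectedMask) &&
      length(object@selectedMask) != length(object@w))
    msg <- c(msg, "selectedMask length must match weight vector")
  if (length(object@featureNames) &&
      length(object@featureNames) != length(object@w))
    msg <- c(msg, "featureNames length must match weight vector")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Geodesic flow kernel model
#'
#' @slot G symmetric positive semidefinite D x D kernel matrix.
#' @slot dStar integer(1); chosen subspace dimension.
#' @slot sdmCurve numeric; subspace disagreement measure per candidate d.
#' @slot principalAngles numeric; angles between source and target subspaces,
#'   non-decreasing in \[0, pi/2\].
#' @slot blocks list with elements PS, PT, RS, U1, U2, V (SVD blocks of the
#'   closed-form kernel).
#'
#' @export
setClass("GFKModel",
  representation(
    G = "matrix",
    dStar = "integer",
    sdmCurve = "numeric",
    principalAngles = "numeric",
    blocks = "list"
  )
)

setValidity("GFKModel", function(object) {
  msg <- character()
  if (nrow(object@G) != ncol(object@G)) msg <- c(msg, "G must be square")
  if (max(abs(object@G - t(object@G))) > 1e-10)
    msg <- c(msg, "G must be symmetric")
  th <- object@principalAngles
  if (is.unsorted(th, strictly = FALSE))
    msg <- c(msg, "principal angles must be non-decreasing")
  if (any(th < -1e-12 | th > pi / 2 + 1e-12))
    msg <- c(msg, "principal angles must lie in [0, pi/2]")
  if (length(msg)) msg else TRUE
})

#' Recursive-elimination feature ranking for one training set
#'
#' @slot eliminationOrder integer; feature indices in removal order (first
#'   entry = first removed = lowest rank).
#' @slot accuracyCurve numeric; internal leave-one-subject-out accuracy when
#'   training on the top-k ranked features, k = 1..n.
#' @slot kStar integer(1); smallest k attaining the maximal accuracy.
#'
#' @export
setClass("FeatureRanking",
  representation(
    eliminationOrder = "integer",
    accuracyCurve = "numeric",
    kStar = "integer"
  )
)

setValidity("FeatureRanking", function(object) {
  n <- length(object@eliminationOrder)
  msg <- character()
  if (!setequal(object@eliminationOrder, seq_len(n)))
    msg <- c(msg, "eliminationOrder must be a permutation of 1..n")
  if (length(object@accuracyCurve) && length(object@accuracyCurve) != n)
    msg <- c(msg, "accuracyCurve length must equal feature count")
  if (length(object@accuracyCurve) && length(object@kStar) == 1L &&
      !is.na(object@kStar)) {
    if (abs(object@accuracyCurve[object@kStar] -
            max(object@accuracyCurve)) > 1e-12)
      msg <- c(msg, "kStar must attain the maximal accuracy")
  }
  if (length(msg)) msg else TRUE
})

#' Per-held-out-subject dynamical feature selection result
#'
#' @slot subjects character; held-out subject per fold.
#' @slot rankings list of [FeatureRanking-class], one per fold.
#' @slot masks list of integer vectors; per-fold indices (into the columns of
#'   the input feature set) surviving NCA selection, in the column order used
#'   by the fold's ranking.
#' @slot accuracies numeric; held-out test accuracy per fold (NA for folds
#'   that failed).
#' @slot details list; per-fold diagnostics (selected features, d*, errors).
#'
#' @export
setClass("DFSResult",
  representation(
    subjects = "character",
    rankings = "list",
    masks = "list",
    accuracies = "numeric",
    details = "list"
  )
)

#' Leave-one-subject-out evaluation report
#'
#' @slot accuracies named numeric; per-held-out-subject accuracy.
#' @slot meanAccuracy numeric(1).
#' @slot sdAccuracy numeric(1).
#' @slot confusion 3 x 3 matrix of pooled confusion counts (true x predicted).
#' @slot pipeline character(1).
#' @slot classifier character(1).
#'
#' @export
setClass("LOSOReport",
  representation(
    accuracies = "numeric",
    meanAccuracy = "numeric",
    sdAccuracy = "numeric",
    confusion = "matrix",
    pipeline = "character",
    classifier = "character"
  )
)

setValidity("LOSOReport", function(object) {
  msg <- character()
  ok <- is.na(object@meanAccuracy) ||
    abs(object@meanAccuracy - mean(object@accuracies, na.rm = TRUE)) < 1e-12
  if (!ok) msg <- c(msg, "stored mean must match accuracy vector")
  if (length(msg)) msg else TRUE
})
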