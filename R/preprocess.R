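#' Three-class label from a 1-9 affective rating
#'
#' Ratings above 5.5 map to the high class (2), ratings below 3.5 to the low
#' class (0), and the closed middle interval \[3.5, 5.5\] to neutral (1).
#' Boundary values 3.5 and 5.5 fall in the neutral class: the outer classes
#' are defined by strict inequalities, so the closed middle interval is the
#' only consistent reading.
#'
#' @param rating numeric vector of ratings in \[1, 9\].
#' @return integer vector: 0 = low, 1 = neutral, 2 = high.
#' @examples
#' assignLabel(c(7, 4, 5.5, 2))
#' @export
assignLabel <- function(rating) {
  if (any(is.na(rating)) || any(rating < 1 | rating > 9))
    stop("ratings must lie in [1, 9]")
  ifelse(rating > 5.5, 2L, ifelse(rating < 3.5, 0L, 1L))
}

#' Butterworth filter specification
#'
#' @param kind `"bandpass"`, `"highpass"` or `"lowpass"`.
#' @param order filter order (>= 1). Filtering is zero-phase
#'   (forward-backward), which doubles the effective order.
#' @param cutoffs cutoff frequencies in Hz; two values for bandpass, one
#'   otherwise.
#' @return a `FilterSpec` list.
#' @examples
#' filterSpec("bandpass", 5, c(4, 45))
#' @export
filterSpec <- function(kind = c("bandpass", "highpass", "lowpass"),
                       order, cutoffs) {
  kind <- match.arg(kind)
  if (order < 1) stop("filter order must be >= 1")
  nc <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs) != nc)
    stop(sprintf("%s filter needs %d cutoff(s)", kind, nc))
  if (kind == "bandpass" && cutoffs[1] >= cutoffs[2])
    stop("bandpass cutoffs must be increasing")
  structure(list(kind = kind, order = as.integer(order),
                 cutoffs = as.numeric(cutoffs)),
            class = "FilterSpec")
}

#' Database-style preprocessing profile
#'
#' Bundled profiles mirror the per-database preprocessing conventions:
#' * `"deap-like"`: 5th-order 4-45 Hz Butterworth bandpass, 128 Hz, no
#'   re-referencing.
#' * `"hci-like"`: common-average re-referencing plus a 7th-order 3 Hz
#'   highpass, 128 Hz; trials are cropped to seconds \[5, 65) before
#'   segmentation.
#' * `"seed-like"`: 7th-order 3 Hz highpass followed by a 7th-order 45 Hz
#'   lowpass, 200 Hz.
#'
#' A bandpass-for-all reading of the filter table also circulates; the
#' profiles follow the per-database prose convention (bandpass only for the
#' deap-like profile). Use `name = "custom"` with an explicit filter list
#' to deviate.
#'
#' @param name profile name.
#' @param targetFs output sampling rate in Hz (downsampling = anti-alias
#'   lowpass + integer decimation, applied after the profile's filters).
#' @param rereference subtract the per-sample average of all channels first?
#' @param filters ordered list of [filterSpec()] objects, applied in order.
#' @param nSegments number of non-overlapping equal segments per trial.
#' @param cropSeconds optional `c(from, to)` in seconds; samples outside the
#'   half-open interval are dropped before segmentation.
#' @return a `PreprocessProfile` list.
#' @examples
#' preprocessProfile("deap-like")
#' @export
preprocessProfile <- function(name = c("deap-like", "hci-like", "seed-like",
                                       "custom"),
                              targetFs = NULL, rereference = NULL,
                              filters = NULL, nSegments = 4L,
                              cropSeconds = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    "deap-like" = list(targetFs = 128, rereference = FALSE,
      filters = list(filterSpec("bandpass", 5, c(4, 45))),
      cropSeconds = NULL),
    "hci-like" = list(targetFs = 128, rereference = TRUE,
      filters = list(filterSpec("highpass", 7, 3)),
      cropSeconds = c(5, 65)),
    "seed-like" = list(targetFs = 200, rereference = FALSE,
      filters = list(filterSpec("highpass", 7, 3),
                     filterSpec("lowpass", 7, 45)),
      cropSeconds = NULL),
    "custom" = list(targetFs = NULL, rereference = FALSE,
      filters = list(), cropSeconds = NULL))
  prof <- list(
    name = name,
    targetFs = if (is.null(targetFs)) defaults$targetFs else targetFs,
    rereference = if (is.null(rereference)) defaults$rereference
                  else rereference,
    filters = if (is.null(filters)) defaults$filters else filters,
    nSegments = as.integer(nSegments),
    cropSeconds = if (is.null(cropSeconds)) defaults$cropSeconds
                  else cropSeconds)
  stopifnot(all(vapply(prof$filters, inherits, logical(1), "FilterSpec")))
  structure(prof, class = "PreprocessProfile")
}

# Zero-phase Butterworth filtering of one channels x samples matrix.
.applyFilter <- function(x, spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoffs >= nyq))
    stop(sprintf("filter cutoff %g Hz at or above Nyquist (%g Hz)",
                 max(spec$cutoffs), nyq))
  type <- switch(spec$kind, bandpass = "pass", highpass = "high",
                 lowpass = "low")
  bf <- signal::butter(spec$order, spec$cutoffs / nyq, type = type)
  t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
}

# Anti-alias lowpass (8th order at 80% of the target Nyquist) + integer
# decimation.
.downsample <- function(x, fs, targetFs) {
  q <- fs / targetFs
  if (abs(q - round(q)) > 1e-9)
    stop("downsampling requires an integer decimation factor")
  q <- round(q)
  if (q == 1L) return(x)
  x <- .applyFilter(x, filterSpec("lowpass", 8, 0.8 * targetFs / 2), fs)
  x[, seq(1, ncol(x), by = q), drop = FALSE]
}

#' Apply a preprocessing profile to a recording set
#'
#' Per trial, in order: optional common-average re-referencing (each sample
#' vector gets zero channel mean), the profile's Butterworth filters applied
#' zero-phase (forward-backward), then downsampling to `targetFs` when it is
#' below the input rate. Cutoffs are validated against the Nyquist rate at
#' the stage where each filter runs.
#'
#' @param rec an [EEGRecordingSet-class].
#' @param profile a [preprocessProfile()].
#' @return an [EEGRecordingSet-class] at `targetFs`.
#' @examples
#' rec <- generateRecordings(synthConfig(nSubjects = 2,
#'   nTrialsPerSubject = 3, trialSeconds = 2, fs = 128))
#' out <- applyProfile(rec, preprocessProfile("deap-like"))
#' @export
applyProfile <- function(rec, profile) {
  stopifnot(methods::is(rec, "EEGRecordingSet"),
            inherits(profile, "PreprocessProfile"))
  fs <- rec@fs
  targetFs <- if (is.null(profile$targetFs)) fs else profile$targetFs
  if (targetFs > fs)
    stop("upsampling is not supported: targetFs exceeds the input rate")
  signals <- lapply(rec@signals, function(trials) {
    lapply(trials, function(x) {
      if (profile$rereference)
        x <- sweep(x, 2, colMeans(x))
      for (spec in profile$filters)
        x <- .applyFilter(x, spec, fs)
      x <- .downsample(x, fs, targetFs)
      rownames(x) <- rec@channelNames
      x
    })
  })
  methods::new("EEGRecordingSet", signals = signals, fs = targetFs,
               channelNames = rec@channelNames, trialInfo = rec@trialInfo)
}

#' Split trials into non-overlapping equal segments
#'
#' Optionally crops each trial to `cropSeconds = c(from, to)` (half-open in
#' seconds) first, then cuts it into `nSegments` equal non-overlapping
#' pieces. When the (cropped) length is not divisible by `nSegments`, the
#' remainder samples are truncated from the end. Each segment inherits its
#' trial's label.
#'
#' @param rec an [EEGRecordingSet-class].
#' @param nSegments segments per trial.
#' @param cropSeconds optional `c(from, to)` crop window in seconds.
#' @return an [EEGSegmentSet-class].
#' @examples
#' rec <- generateRecordings(synthConfig(nSubjects = 2,
#'   nTrialsPerSubject = 3, trialSeconds = 4, fs = 128))
#' segmentTrials(rec, 4)
#' @export
segmentTrials <- function(rec, nSegments = 4L, cropSeconds = NULL) {
  stopifnot(methods::is(rec, "EEGRecordingSet"))
  nSegments <- as.integer(nSegments)
  if (nSegments < 1) stop("nSegments must be >= 1")
  segments <- list()
  info <- list()
  k <- 0L
  row <- 0L
  for (s in seq_along(rec@signals)) {
    for (tr in seq_along(rec@signals[[s]])) {
      row <- row + 1L
      x <- rec@signals[[s]][[tr]]
      if (!is.null(cropSeconds)) {
        from <- floor(cropSeconds[1] * rec@fs) + 1L
        to <- floor(cropSeconds[2] * rec@fs)
        if (to > ncol(x) || from >= to)
          stop("trial too short for the requested crop window")
        x <- x[, from:to, drop = FALSE]
      }
      segLen <- ncol(x) %/% nSegments
      if (segLen < 1) stop("trial too short for the requested segmentation")
      for (g in seq_len(nSegments)) {
        k <- k + 1L
        segments[[k]] <- x[, ((g - 1L) * segLen + 1L):(g * segLen),
                           drop = FALSE]
        info[[k]] <- data.frame(
          subject_id = rec@trialInfo$subject_id[row],
          trial = rec@trialInfo$trial[row],
          segment = g,
          label = rec@trialInfo$label[row],
          stringsAsFactors = FALSE)
      }
    }
  }
  methods::new("EEGSegmentSet", segments = segments, fs = rec@fs,
               channelNames = rec@channelNames,
               segmentInfo = do.call(rbind, info))
}
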