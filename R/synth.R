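#' Configuration of the synthetic multi-subject EEG generator
#'
#' Defines a study layout (subjects x trials x channels, sampling rate,
#' trial length), the class-dependent band-power structure and the strength
#' of subject-specific distribution shifts. Defaults emulate a 32-subject,
#' 40-trial, 60-s, 128 Hz layout with rating-style labels.
#'
#' `bandEffect` is a named list mapping each band (theta/alpha/beta/gamma) to
#' a length-3 multiplier vector for the (low, neutral, high) classes. The
#' default raises beta/gamma power and lowers alpha power for the high class,
#' the canonical direction of affective band-power modulation.
#'
#' @param nSubjects number of subjects.
#' @param nTrialsPerSubject trials per subject (balanced over 3 classes).
#' @param trialSeconds trial duration in seconds.
#' @param fs sampling rate in Hz; must exceed 90 so the 45 Hz gamma edge is
#'   below Nyquist.
#' @param nChannels number of channels (default 32, named by the bundled
#'   10-20 montage; other counts get synthetic names).
#' @param classScheme `"rating"` (emit 1-9 ratings inside each class's
#'   interval) or `"categorical"` (labels only).
#' @param bandEffect named list of per-class amplitude multipliers per band.
#' @param subjectShiftSd dimensionless spread of the per-subject log-normal
#'   gain and per-band scaling; also scales a per-subject DC offset (10 uV
#'   per unit).
#' @param noiseSd white-noise standard deviation in uV.
#' @param baseAmplitude named list of per-band baseline amplitudes in uV.
#' @param seed integer seed; every trial is generated under a counter-derived
#'   sub-seed so the set is reproducible trial by trial.
#' @return a validated `SynthConfig` list.
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nTrialsPerSubject = 6, trialSeconds = 4)
#' @export
synthConfig <- function(nSubjects = 32L,
                        nTrialsPerSubject = 40L,
                        trialSeconds = 60,
                        fs = 128,
                        nChannels = 32L,
                        classScheme = c("rating", "categorical"),
                        bandEffect = list(
                          theta = c(1, 1, 1),
                          alpha = c(1.25, 1, 0.8),
                          beta  = c(0.8, 1, 1.25),
                          gamma = c(0.8, 1, 1.25)
                        ),
                        subjectShiftSd = 0.3,
                        noiseSd = 2,
                        baseAmplitude = list(theta = 6, alpha = 10,
                                             beta = 5, gamma = 3),
                        seed = 1L) {
  classScheme <- match.arg(classScheme)
  if (nChannels < 2) stop("nChannels must be >= 2")
  if (fs <= 90) stop("fs must exceed 90 Hz (45 Hz gamma edge below Nyquist)")
  nSamples <- trialSeconds * fs
  if (abs(nSamples - round(nSamples)) > 1e-9)
    stop("trialSeconds * fs must be an integer sample count")
  if (!setequal(names(bandEffect), names(.BANDS)))
    stop("bandEffect must name exactly the bands theta, alpha, beta, gamma")
  if (!all(vapply(bandEffect, length, integer(1)) == 3L))
    stop("each bandEffect entry needs 3 per-class multipliers")
  if (!setequal(names(baseAmplitude), names(.BANDS)))
    stop("baseAmplitude must name exactly the bands theta, alpha, beta, gamma")
  channels <- if (nChannels == 32L) .MONTAGE32 else
    sprintf("ch%02d", seq_len(nChannels))
  structure(list(
    nSubjects = as.integer(nSubjects),
    nTrialsPerSubject = as.integer(nTrialsPerSubject),
    trialSeconds = trialSeconds,
    fs = fs,
    nChannels = as.integer(nChannels),
    channelNames = channels,
    classScheme = classScheme,
    bandEffect = bandEffect,
    subjectShiftSd = subjectShiftSd,
    noiseSd = noiseSd,
    baseAmplitude = baseAmplitude,
    seed = as.integer(seed)
  ), class = "SynthConfig")
}

# Counter-based sub-seed: reproducible per (subject, trial) independent of
# generation order. Kept below 2^31 - 1.
.subSeed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 7919 + j * 104729) %%
               2147483647)
}

#' Generate synthetic multi-subject EEG with a known cross-subject gap
#'
#' Each trial is a sum of band-limited oscillations (theta, alpha, beta,
#' gamma): per channel, one sinusoid per band with a trial-level center
#' frequency jittered by up to 1 Hz inside the band and a channel-level
#' random phase. Per-band amplitudes are `baseAmplitude * bandEffect[class]`,
#' multiplied by a per-subject gain `exp(Normal(0, subjectShiftSd))` and a
#' per-subject, per-band scaling of the same spread; a per-subject DC offset
#' and white noise are added. Trial labels are balanced over the three
#' classes by construction, so chance level is exactly 1/3.
#'
#' @param config a [synthConfig()] object.
#' @return an [EEGRecordingSet-class].
#' @examples
#' rec <- generateRecordings(synthConfig(nSubjects = 2,
#'   nTrialsPerSubject = 6, trialSeconds = 2, fs = 128))
#' rec
#' @export
generateRecordings <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  ns <- config$nSubjects
  nt <- config$nTrialsPerSubject
  n <- round(config$trialSeconds * config$fs)
  tgrid <- (seq_len(n) - 1) / config$fs
  bands <- .BANDS
  signals <- vector("list", ns)
  info <- vector("list", ns)
  for (s in seq_len(ns)) {
    set.seed(.subSeed(config$seed, s))
    gain <- exp(stats::rnorm(1, 0, config$subjectShiftSd))
    bandScale <- exp(stats::rnorm(length(bands), 0, config$subjectShiftSd))
    names(bandScale) <- names(bands)
    offset <- stats::rnorm(1, 0, 10 * config$subjectShiftSd)
    # balanced labels, order shuffled per subject
    labels <- sample(rep(0:2, length.out = nt))
    trials <- vector("list", nt)
    ratings <- rep(NA_real_, nt)
    for (tr in seq_len(nt)) {
      set.seed(.subSeed(config$seed, s, tr))
      cls <- labels[tr] + 1L
      x <- matrix(stats::rnorm(config$nChannels * n, 0, config$noiseSd),
                  config$nChannels, n)
      for (b in names(bands)) {
        lo <- bands[[b]][1]; hi <- bands[[b]][2]
        f0 <- stats::runif(1, max(lo, (lo + hi) / 2 - 1),
                           min(hi, (lo + hi) / 2 + 1))
        amp <- config$baseAmplitude[[b]] * config$bandEffect[[b]][cls] *
          gain * bandScale[b]
        phase <- stats::runif(config$nChannels, 0, 2 * pi)
        x <- x + amp * sin(outer(phase, 2 * pi * f0 * tgrid, `+`))
      }
      x <- x + offset
      rownames(x) <- config$channelNames
      trials[[tr]] <- x
      if (config$classScheme == "rating") {
        ratings[tr] <- switch(cls,
          stats::runif(1, 1, 3.499),
          stats::runif(1, 3.5, 5.5),
          stats::runif(1, 5.501, 9))
      }
    }
    signals[[s]] <- trials
    info[[s]] <- data.frame(
      subject_id = sprintf("S%02d", s),
      trial = seq_len(nt),
      rating = ratings,
      label = labels,
      stringsAsFactors = FALSE
    )
  }
  methods::new("EEGRecordingSet",
    signals = signals,
    fs = config$fs,
    channelNames = config$channelNames,
    trialInfo = do.call(rbind, info))
}

#' Construct an EEGFeatureSet from an instances x features matrix
#'
#' @param values numeric matrix, instances x named features.
#' @param subjectIds character/factor, one per instance.
#' @param labels integer class labels (0/1/2), one per instance.
#' @param metadata optional list stored in the object's metadata.
#' @return an [EEGFeatureSet-class].
#' @examples
#' fs <- EEGFeatureSet(matrix(rnorm(20), 5, 4,
#'     dimnames = list(NULL, paste0("f", 1:4))),
#'   subjectIds = rep(c("a", "b"), c(2, 3)), labels = c(0, 1, 2, 0, 1))
#' @export
EEGFeatureSet <- function(values, subjectIds, labels, metadata = list()) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  if (nrow(values) != length(subjectIds) || nrow(values) != length(labels))
    stop("subjectIds and labels must have one entry per instance (row)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    colData = S4Vectors::DataFrame(
      subject_id = as.character(subjectIds),
      label = as.integer(labels)))
  obj <- methods::new("EEGFeatureSet", se)
  S4Vectors::metadata(obj) <- metadata
  obj
}

#' Planted-signal feature sets for selector benchmarking
#'
#' Generates instance-level feature data directly (bypassing the raw-signal
#' path) with a small set of informative columns whose class-conditional
#' means are separated by `effectSize` standard deviations, plus pure-noise
#' columns. Every column additionally receives a per-subject random offset of
#' spread `shiftSd` so a genuine cross-subject domain gap exists; informative
#' structure is shared across subjects. Labels are balanced by construction.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param nPerSubject instances per subject.
#' @param nInformative number of informative features.
#' @param nNoise number of pure-noise features.
#' @param effectSize class-mean separation in within-class SD units.
#' @param shiftSd spread of the per-subject, per-feature offsets.
#' @param seed integer seed.
#' @return an [EEGFeatureSet-class]; `metadata(x)$informative` holds the
#'   indices of the planted columns.
#' @examples
#' fs <- plantedFeatureSet(nSubjects = 4, nPerSubject = 9, seed = 1)
#' S4Vectors::metadata(fs)$informative
#' @export
plantedFeatureSet <- function(nSubjects = 8L, nPerSubject = 15L,
                              nInformative = 5L, nNoise = 25L,
                              effectSize = 1.5, shiftSd = 0.3,
                              seed = 1L) {
  p <- nInformative + nNoise
  classMeans <- outer(0:2 - 1, seq_len(nInformative)^0) * effectSize
  X <- matrix(NA_real_, nSubjects * nPerSubject, p)
  subj <- character(nSubjects * nPerSubject)
  y <- integer(nSubjects * nPerSubject)
  row <- 0L
  for (s in seq_len(nSubjects)) {
    set.seed(.subSeed(seed, s))
    shift <- stats::rnorm(p, 0, shiftSd)
    labels <- sample(rep(0:2, length.out = nPerSubject))
    for (i in seq_len(nPerSubject)) {
      row <- row + 1L
      x <- stats::rnorm(p)
      if (nInformative > 0)
        x[seq_len(nInformative)] <- x[seq_len(nInformative)] +
          classMeans[labels[i] + 1L, ]
      X[row, ] <- x + shift
      subj[row] <- sprintf("S%02d", s)
      y[row] <- labels[i]
    }
  }
  colnames(X) <- c(sprintf("signal%02d", seq_len(nInformative)),
                   sprintf("noise%02d", seq_len(nNoise)))
  EEGFeatureSet(X, subj, y,
                metadata = list(informative = seq_len(nInformative)))
}
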