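# Shared fixtures, all generated in code.

# Small recording: 2 subjects x 6 trials of 8 s at 128 Hz (2 s segments
# after quartering).
tinyRecording <- function(seed = 1, nSubjects = 2, nTrials = 6,
                          trialSeconds = 8, fs = 128, ...) {
  generateRecordings(synthConfig(
    nSubjects = nSubjects, nTrialsPerSubject = nTrials,
    trialSeconds = trialSeconds, fs = fs, seed = seed, ...))
}

# One 32-channel segment holding a given per-channel signal matrix.
namedSegment <- function(x) {
  stopifnot(nrow(x) == 32)
  rownames(x) <- montage32()
  x
}

# Pure sine on all 32 channels.
toneSegment <- function(freq, fs = 128, seconds = 2, amplitude = 1) {
  t <- (seq_len(fs * seconds) - 1) / fs
  namedSegment(matrix(rep(amplitude * sin(2 * pi * freq * t), 32),
                      32, byrow = TRUE))
}

# Numerical quadrature of the geodesic projector integral (independent
# oracle for the closed-form kernel): trapezoid rule on [0, 1].
quadratureKernel <- function(model, nPoints = 2000) {
  ts <- seq(0, 1, length.out = nPoints + 1)
  acc <- 0
  for (i in seq_along(ts)) {
    P <- geodesicPoint(model, ts[i])
    w <- if (i == 1 || i == length(ts)) 0.5 else 1
    acc <- acc + w * P %*% t(P)
  }
  acc / nPoints
}

# Mean band power of one channel via the package periodogram path.
channelBandPower <- function(x, band, fs) {
  seg <- namedSegment(matrix(rep(x, 32), 32, byrow = TRUE))
  unname(extractPsdFeatures(seg, bandScheme(), fs)[
    paste0("cl.psd.", band, ".Fp1")])
}
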