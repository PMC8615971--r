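# --- per-channel helpers ----------------------------------------------------

# Shannon entropy (nats) of the 16-equal-width-bin amplitude histogram over
# the channel's own min..max range; constant channels get 0.
.shannonEntropy <- function(x, nbins = 16L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  counts <- tabulate(pmin(
    as.integer((x - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L, nbins),
    nbins = nbins)
  p <- counts / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Sign changes of the mean-removed signal per sample transition.
.zeroCrossingRate <- function(x) {
  x <- x - mean(x)
  s <- sign(x)
  nz <- s != 0
  s <- s[nz]
  if (length(s) < 2) return(0)
  sum(s[-1] != s[-length(s)]) / (length(x) - 1)
}

# 3rd and 4th standardized moments; kurtosis is the plain m4/m2^2
# (Gaussian -> 3). Degenerate (constant) channels yield 0.
.skewKurt <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2)
}

# One-sided periodogram (rectangular window) of one channel.
# Returns data.frame(freq, power); DC bin excluded.
.periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  idx <- 2:(half + 1)                      # skip DC
  p <- (2 / (fs * n)) * Mod(X[idx])^2
  if (n %% 2 == 0) p[half] <- p[half] / 2  # Nyquist bin is not doubled
  list(freq = (idx - 1) * fs / n, power = p)
}

# Mean periodogram power over the bins whose frequency falls inside the band
# (inclusive edges).
.bandPower <- function(pg, band) {
  inband <- pg$freq >= band[1] & pg$freq <= band[2]
  if (!any(inband)) return(0)
  mean(pg$power[inband])
}

# --- exported per-segment extractors ----------------------------------------

#' Time-domain features of one segment (5 per channel)
#'
#' Per channel: sample variance ("variation"), zero-crossing rate of the
#' mean-removed signal (sign changes / (samples - 1)), Shannon entropy of
#' the 16-bin amplitude histogram (nats), kurtosis (4th standardized moment,
#' Gaussian reference value 3) and skewness. Features are ordered
#' feature-major: all variances, then all zero-crossing rates, and so on.
#'
#' @param segment channels x samples numeric matrix with channel rownames.
#' @return named numeric vector of length `5 * nrow(segment)` (160 for the
#'   32-channel montage), names `cl.time.<feature>.<channel>`.
#' @examples
#' seg <- matrix(rnorm(32 * 256), 32, 256, dimnames = list(montage32()))
#' length(extractTimeFeatures(seg))
#' @export
extractTimeFeatures <- function(segment) {
  if (ncol(segment) < 8) stop("segment needs >= 8 samples per channel")
  ch <- rownames(segment)
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_len(nrow(segment)))
  variance <- apply(segment, 1, stats::var)
  zcr <- apply(segment, 1, .zeroCrossingRate)
  ent <- apply(segment, 1, .shannonEntropy)
  sk <- apply(segment, 1, .skewKurt)
  out <- c(variance, zcr, ent, sk["kurtosis", ], sk["skewness", ])
  names(out) <- c(paste0("cl.time.variance.", ch),
                  paste0("cl.time.zcr.", ch),
                  paste0("cl.time.entropy.", ch),
                  paste0("cl.time.kurtosis.", ch),
                  paste0("cl.time.skewness.", ch))
  out
}

#' Spectral features of one segment (204 for the 32-channel montage)
#'
#' Three blocks, in order:
#' 1. average band power of the four bands per channel (band-major;
#'    4 x 32 = 128), from the one-sided rectangular-window periodogram with
#'    inclusive band-edge bin membership;
#' 2. hemispheric band-power differences `p(right) - p(left)` for the 14
#'    left/right electrode pairs in each of the four asymmetry bands
#'    (band-major; 4 x 14 = 56);
#' 3. 20 power ratios: `Fz/(AF3+AF4)`, `Cz/Fz`, `Pz/Cz`, `Oz/Pz` within
#'    each of the four bands (16) plus the four theta/alpha cross-band
#'    ratios `AFz(t)/Pz(a)`, `AFz(t)/Cz(a)`, `Cz(t)/Pz(a)`, `Cz(t)/Oz(a)`,
#'    where `AFz` power is the mean of AF3 and AF4 (that site is absent
#'    from the 32-channel montage). Zero denominators give 0 with a warning.
#'
#' @param segment channels x samples matrix with channel rownames.
#' @param scheme a [bandScheme()].
#' @param fs sampling rate in Hz.
#' @return named numeric vector (128 + 56 + 20 = 204 values for the bundled
#'   montage).
#' @examples
#' seg <- matrix(rnorm(32 * 256), 32, 256, dimnames = list(montage32()))
#' length(extractPsdFeatures(seg, bandScheme(), 128))
#' @export
extractPsdFeatures <- function(segment, scheme = bandScheme(), fs) {
  if (ncol(segment) < 2 * fs) stop("segment must be at least 2 s long")
  ch <- rownames(segment)
  if (is.null(ch)) stop("segment needs channel rownames")
  pgs <- apply(segment, 1, .periodogram, fs = fs, simplify = FALSE)
  names(pgs) <- ch
  bp <- function(channel, band) .bandPower(pgs[[channel]], band)

  out <- numeric(0)
  # (a) average band power, band-major
  for (b in names(scheme$bands)) {
    v <- vapply(ch, bp, numeric(1), band = scheme$bands[[b]])
    names(v) <- paste0("cl.psd.", b, ".", ch)
    out <- c(out, v)
  }
  # (b) hemispheric differences, band-major over the asymmetry bands
  for (b in names(scheme$asymBands)) {
    band <- scheme$asymBands[[b]]
    v <- vapply(.ASYM_PAIRS, function(pr) bp(pr[2], band) - bp(pr[1], band),
                numeric(1))
    names(v) <- vapply(.ASYM_PAIRS, function(pr)
      paste0("cl.diff.", b, ".", pr[2], "-", pr[1]), character(1))
    out <- c(out, v)
  }
  # (c) power ratios
  ratio <- function(num, den, name) {
    if (den <= 0) {
      warning(sprintf("zero denominator in power ratio %s; set to 0", name))
      return(stats::setNames(0, name))
    }
    stats::setNames(num / den, name)
  }
  for (b in names(scheme$bands)) {
    band <- scheme$bands[[b]]
    out <- c(out,
      ratio(bp("Fz", band), bp("AF3", band) + bp("AF4", band),
            paste0("cl.ratio.", b, ".Fz_AF3AF4")),
      ratio(bp("Cz", band), bp("Fz", band), paste0("cl.ratio.", b, ".Cz_Fz")),
      ratio(bp("Pz", band), bp("Cz", band), paste0("cl.ratio.", b, ".Pz_Cz")),
      ratio(bp("Oz", band), bp("Pz", band), paste0("cl.ratio.", b, ".Oz_Pz")))
  }
  th <- scheme$bands$theta; al <- scheme$bands$alpha
  afzTheta <- (bp("AF3", th) + bp("AF4", th)) / 2
  out <- c(out,
    ratio(afzTheta, bp("Pz", al), "cl.ratio.cross.AFzTheta_PzAlpha"),
    ratio(afzTheta, bp("Cz", al), "cl.ratio.cross.AFzTheta_CzAlpha"),
    ratio(bp("Cz", th), bp("Pz", al), "cl.ratio.cross.CzTheta_PzAlpha"),
    ratio(bp("Cz", th), bp("Oz", al), "cl.ratio.cross.CzTheta_OzAlpha"))
  out
}

#' Differential entropy features of one segment (4 bands x channels)
#'
#' Per channel and band: the channel is bandpass filtered to the band
#' (5th-order Butterworth, zero-phase), the sample variance of the filtered
#' series is taken, and the differential entropy of a Gaussian with that
#' variance is returned, `h = 0.5 * log(2 * pi * e * var)` in nats.
#' Variances below 1e-12 are clamped there with a warning. Ordered
#' band-major then channel.
#'
#' @inheritParams extractPsdFeatures
#' @return named numeric vector (`de.<band>.<channel>`; 128 values for the
#'   32-channel montage).
#' @examples
#' seg <- matrix(rnorm(32 * 256), 32, 256, dimnames = list(montage32()))
#' length(extractDeFeatures(seg, bandScheme(), 128))
#' @export
extractDeFeatures <- function(segment, scheme = bandScheme(), fs) {
  if (ncol(segment) < 2 * fs) stop("segment must be at least 2 s long")
  ch <- rownames(segment)
  if (is.null(ch)) ch <- sprintf("ch%02d", seq_len(nrow(segment)))
  out <- numeric(0)
  for (b in names(scheme$bands)) {
    filtered <- .applyFilter(segment,
                             filterSpec("bandpass", 5, scheme$bands[[b]]),
                             fs)
    v <- apply(filtered, 1, stats::var)
    if (any(v < 1e-12)) {
      warning("band variance below 1e-12 clamped for differential entropy")
      v <- pmax(v, 1e-12)
    }
    h <- 0.5 * log(2 * pi * exp(1) * v)
    names(h) <- paste0("de.", b, ".", ch)
    out <- c(out, h)
  }
  out
}

#' Extract a feature matrix from a segment set
#'
#' The CL (classical) set stacks, in fixed order, the 160 time-domain
#' features, 128 band powers, 56 hemispheric differences and 20 power
#' ratios (364 columns for the 32-channel montage). The DE set holds the
#' 128 differential entropies. Row order preserves (subject, trial,
#' segment) order; feature names are stable for a given montage.
#'
#' @param segset an [EEGSegmentSet-class].
#' @param which `"CL"` or `"DE"`.
#' @param scheme a [bandScheme()].
#' @return an [EEGFeatureSet-class].
#' @examples
#' rec <- generateRecordings(synthConfig(nSubjects = 2,
#'   nTrialsPerSubject = 3, trialSeconds = 8, fs = 128))
#' fs <- extractFeatures(segmentTrials(rec, 4), "DE")
#' dim(featureValues(fs))
#' @export
extractFeatures <- function(segset, which = c("CL", "DE"),
                            scheme = bandScheme()) {
  stopifnot(methods::is(segset, "EEGSegmentSet"))
  which <- match.arg(which)
  extractor <- function(seg) {
    if (which == "CL")
      c(extractTimeFeatures(seg),
        extractPsdFeatures(seg, scheme, segset@fs))
    else
      extractDeFeatures(seg, scheme, segset@fs)
  }
  if (!length(segset@segments)) {
    # preserve the full feature-name header for the montage
    dummy <- matrix(stats::rnorm(length(segset@channelNames) *
                                   as.integer(4 * segset@fs)),
                    length(segset@channelNames),
                    dimnames = list(segset@channelNames, NULL))
    nms <- names(extractor(dummy))
    return(EEGFeatureSet(matrix(numeric(0), 0, length(nms),
                                dimnames = list(NULL, nms)),
                         character(0), integer(0)))
  }
  rows <- lapply(segset@segments, extractor)
  X <- do.call(rbind, rows)
  EEGFeatureSet(X, segset@segmentInfo$subject_id, segset@segmentInfo$label,
                metadata = list(featureSet = which))
}

#' The bundled 32-channel 10-20 montage
#'
#' @return character vector of the 32 electrode names in canonical order.
#' @examples
#' head(montage32())
#' @export
montage32 <- function() .MONTAGE32
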