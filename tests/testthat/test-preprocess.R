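test_that("ratings map to the three classes with a closed middle interval", {
  expect_identical(assignLabel(7.0), 2L)
  expect_identical(assignLabel(4.0), 1L)
  expect_identical(assignLabel(5.5), 1L)
  expect_identical(assignLabel(3.5), 1L)
  expect_identical(assignLabel(c(1, 3.49, 5.51, 9)), c(0L, 0L, 2L, 2L))
  expect_error(assignLabel(0.5), "\\[1, 9\\]")
  expect_error(assignLabel(9.2), "\\[1, 9\\]")
})

test_that("the 4-45 Hz bandpass attenuates a 1 Hz tone and passes 10 Hz", {
  fs <- 128
  t <- (0:(8 * fs - 1)) / fs
  mk <- function(freq) {
    sig <- matrix(rep(sin(2 * pi * freq * t), 32), 32, byrow = TRUE)
    rownames(sig) <- montage32()
    methods::new("EEGRecordingSet",
      signals = list(list(sig)), fs = fs, channelNames = montage32(),
      trialInfo = data.frame(subject_id = "S01", trial = 1L,
                             rating = NA_real_, label = 1L))
  }
  prof <- preprocessProfile("deap-like")
  lowOut <- applyProfile(mk(1), prof)@signals[[1]][[1]][1, ]
  passOut <- applyProfile(mk(10), prof)@signals[[1]][[1]][1, ]
  # discard filter edge transients before measuring amplitude
  core <- (2 * fs):(6 * fs)
  attenDb <- 20 * log10(max(abs(lowOut[core])))
  expect_lt(attenDb, -20)
  expect_lt(abs(max(abs(passOut[core])) - 1), 0.05)
})

test_that("common-average re-referencing removes common-mode signals", {
  x <- matrix(5, 32, 256, dimnames = list(montage32()))
  rec <- methods::new("EEGRecordingSet",
    signals = list(list(x)), fs = 128, channelNames = montage32(),
    trialInfo = data.frame(subject_id = "S01", trial = 1L,
                           rating = NA_real_, label = 0L))
  prof <- preprocessProfile("custom", targetFs = 128, rereference = TRUE)
  out <- applyProfile(rec, prof)@signals[[1]][[1]]
  expect_lt(max(abs(out)), 1e-9)
})

test_that("profile output respects the target rate and zero channel mean", {
  rec <- tinyRecording(seed = 4, fs = 256, trialSeconds = 4)
  prof <- preprocessProfile("hci-like")   # reref + 3 Hz highpass, 128 Hz
  out <- applyProfile(rec, prof)
  expect_equal(samplingRate(out), 128)
  expect_equal(ncol(out@signals[[1]][[1]]), 4 * 128)
  # rereferencing happened before filtering; filtered output keeps zero
  # channel mean because the filter is linear and channel-wise identical
  cm <- colMeans(out@signals[[1]][[1]])
  expect_lt(max(abs(cm)), 1e-6 * max(abs(out@signals[[1]][[1]])))
})

test_that("filter cutoffs above Nyquist are rejected", {
  rec <- tinyRecording(seed = 4, fs = 128, trialSeconds = 2)
  bad <- preprocessProfile("custom", targetFs = 128,
    filters = list(filterSpec("lowpass", 4, 70)))
  expect_error(applyProfile(rec, bad), "Nyquist")
})

test_that("bandpass filtering is idempotent once out-of-band is removed", {
  fs <- 128
  t <- (0:(8 * fs - 1)) / fs
  # in-band tone plus slow drift and a 55 Hz tone the filter must remove
  x <- matrix(rep(sin(2 * pi * 10 * t) + 2 * sin(2 * pi * 0.5 * t) +
                    sin(2 * pi * 55 * t), 2), 2, byrow = TRUE)
  once <- mfdfs:::.applyFilter(x, filterSpec("bandpass", 5, c(4, 45)), fs)
  twice <- mfdfs:::.applyFilter(once, filterSpec("bandpass", 5, c(4, 45)), fs)
  core <- (2 * fs):(6 * fs)
  changeOnce <- max(abs(once[1, core] - x[1, core]))
  changeTwice <- max(abs(twice[1, core] - once[1, core]))
  expect_lt(changeTwice, 0.01 * changeOnce)
  # and the surviving in-band tone keeps its amplitude
  expect_lt(abs(max(abs(twice[1, core])) - 1), 0.05)
})

test_that("segmentation counts match the database-shaped layouts", {
  # deap-like: 32 subjects x 40 trials x 4 segments = 5120 (structure only;
  # trials kept short for speed)
  rec <- tinyRecording(seed = 1, nSubjects = 32, nTrials = 40,
                       trialSeconds = 1, fs = 128)
  expect_equal(length(segmentTrials(rec, 4)@segments), 5120)
  rec2 <- tinyRecording(seed = 2, nSubjects = 24, nTrials = 20,
                        trialSeconds = 1, fs = 128)
  expect_equal(length(segmentTrials(rec2, 4)@segments), 1920)
  rec3 <- tinyRecording(seed = 3, nSubjects = 15, nTrials = 45,
                        trialSeconds = 1, fs = 128)
  expect_equal(length(segmentTrials(rec3, 4)@segments), 2700)
})

test_that("segments are equal, non-overlapping and reconstruct the trial", {
  rec <- tinyRecording(seed = 6, nSubjects = 1, nTrials = 1,
                       trialSeconds = 60, fs = 128)
  seg <- segmentTrials(rec, 4)
  expect_equal(length(seg@segments), 4)
  expect_true(all(vapply(seg@segments, ncol, integer(1)) == 1920))
  expect_identical(do.call(cbind, seg@segments), rec@signals[[1]][[1]])
})

test_that("cropping keeps the 5-65 s window before segmentation", {
  rec <- tinyRecording(seed = 6, nSubjects = 1, nTrials = 1,
                       trialSeconds = 70, fs = 128)
  seg <- segmentTrials(rec, 4, cropSeconds = c(5, 65))
  expect_equal(ncol(seg@segments[[1]]), 60 * 128 / 4)
  full <- rec@signals[[1]][[1]][, (5 * 128 + 1):(65 * 128)]
  expect_identical(do.call(cbind, seg@segments), full)
  short <- tinyRecording(seed = 6, nSubjects = 1, nTrials = 1,
                         trialSeconds = 10, fs = 128)
  expect_error(segmentTrials(short, 4, cropSeconds = c(5, 65)), "crop")
})

test_that("segment labels replicate the trial label histogram", {
  rec <- tinyRecording(seed = 8, nSubjects = 3, nTrials = 9,
                       trialSeconds = 1, fs = 128)
  seg <- segmentTrials(rec, 4)
  expect_equal(table(seg@segmentInfo$label),
               table(rec@trialInfo$label) * 4, ignore_attr = TRUE)
})

test_that("non-divisible trials are truncated from the end", {
  x <- matrix(seq_len(2 * 10), 2, 10)
  rec <- methods::new("EEGRecordingSet",
    signals = list(list(x)), fs = 10, channelNames = c("a", "b"),
    trialInfo = data.frame(subject_id = "S01", trial = 1L,
                           rating = NA_real_, label = 0L))
  seg <- segmentTrials(rec, 3)
  expect_true(all(vapply(seg@segments, ncol, integer(1)) == 3))
  expect_identical(do.call(cbind, seg@segments), x[, 1:9])
})
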