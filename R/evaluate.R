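# Leave-one-subject-out evaluation harness: one fold per subject,
# segment-level accuracy, mean and across-subject standard deviation, and
# paired t-tests between pipelines.

.confusion3 <- function(truth, pred) {
  tab <- table(factor(truth, levels = 0:2), factor(pred, levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(true = 0:2, predicted = 0:2))
  m
}

#' Leave-one-subject-out evaluation of a pipeline
#'
#' One fold per subject; the fold's accuracy is the fraction of the
#' held-out subject's instances classified correctly. Pipelines:
#' * `"raw"` - z-score on the training fold, train the classifier
#'   directly;
#' * `"nca-gfk-only"` - NCA feature selection plus GFK transform, then the
#'   classifier (no recursive elimination);
#' * `"mfdfs"` - the full pipeline via [runDfs()].
#'
#' All training statistics (standardization, NCA weights, subspaces) come
#' from the training fold only; the held-out subject's labels are used for
#' scoring alone. With a fixed `seed` the run is reproducible.
#'
#' @param features an [EEGFeatureSet-class] with >= 3 subjects.
#' @param pipeline `"mfdfs"`, `"nca-gfk-only"` or `"raw"`.
#' @param spec a [classifierSpec()].
#' @param ncaCfg,gfkCfg pipeline options, see [runDfs()].
#' @param seed integer seed.
#' @return a [LOSOReport-class].
#' @examples
#' fsyn <- plantedFeatureSet(4, 9, 2, 4, seed = 1)
#' runLoso(fsyn, "raw", classifierSpec("dt"))
#' @export
runLoso <- function(features, pipeline = c("mfdfs", "nca-gfk-only", "raw"),
                    spec = classifierSpec("rf"), ncaCfg = list(),
                    gfkCfg = list(), seed = 1L) {
  stopifnot(methods::is(features, "EEGFeatureSet"))
  pipeline <- match.arg(pipeline)
  X <- featureValues(features)
  y <- classLabels(features)
  subj <- subjectIds(features)
  subjects <- unique(subj)
  if (length(subjects) < 3) stop("evaluation needs >= 3 subjects")
  confusion <- matrix(0L, 3, 3, dimnames = list(true = 0:2, predicted = 0:2))
  if (pipeline == "mfdfs") {
    dfsRes <- runDfs(features, spec, ncaCfg = ncaCfg, gfkCfg = gfkCfg,
                     seed = seed)
    acc <- dfsRes@accuracies
    names(acc) <- dfsRes@subjects
  } else {
    cfg <- utils::modifyList(list(
      lambda = 0.01, sigma = 1, maxIter = 50L, tol = 1e-6,
      thresholdFrac = 0.02, minK = 27L, maxK = 38L), ncaCfg)
    gcfg <- utils::modifyList(list(d = NULL, dMax = NULL, epsilon = 1e-3),
                              gfkCfg)
    acc <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
    for (f in seq_along(subjects)) {
      s <- subjects[f]
      foldSpec <- spec
      foldSpec$seed <- .subSeed(seed, f)
      tr <- subj != s
      std <- .standardizer(X[tr, , drop = FALSE])
      Xtr <- std(X[tr, , drop = FALSE]); Xte <- std(X[!tr, , drop = FALSE])
      ytr <- y[tr]
      if (pipeline == "nca-gfk-only") {
        nca <- fitNca(Xtr, ytr, lambda = cfg$lambda, sigma = cfg$sigma,
                      maxIter = cfg$maxIter, tol = cfg$tol)
        nca <- selectFeatures(nca, cfg$thresholdFrac, cfg$minK, cfg$maxK)
        sel <- which(nca@selectedMask)
        gfk <- fitGfk(Xtr[, sel, drop = FALSE], Xte[, sel, drop = FALSE],
                      d = gcfg$d, dMax = gcfg$dMax, epsilon = gcfg$epsilon)
        Xtr <- transformFeatures(gfk, Xtr[, sel, drop = FALSE])
        Xte <- transformFeatures(gfk, Xte[, sel, drop = FALSE])
      }
      fit <- fitClassifier(foldSpec, Xtr, ytr)
      pred <- predictClassifier(fit, Xte)
      acc[f] <- mean(pred == y[!tr])
      confusion <- confusion + .confusion3(y[!tr], pred)
    }
  }
  methods::new("LOSOReport",
    accuracies = acc,
    meanAccuracy = mean(acc, na.rm = TRUE),
    sdAccuracy = stats::sd(acc, na.rm = TRUE),
    confusion = confusion,
    pipeline = pipeline,
    classifier = spec$name)
}

#' Paired t-test between per-subject accuracy vectors
#'
#' Two-sided paired t-test on the per-subject differences with
#' `df = n - 1`. Identical vectors return `t = 0, p = 1`; zero-variance
#' nonzero-mean differences return `p = 0` with an infinite statistic and a
#' warning.
#'
#' @param accA,accB equal-length per-subject accuracy vectors (n >= 3).
#' @return list with `t`, `p`, `df`.
#' @examples
#' pairedT(c(.5, .6, .7), c(.4, .5, .65))
#' @export
pairedT <- function(accA, accB) {
  if (length(accA) != length(accB)) stop("vectors must have equal length")
  n <- length(accA)
  if (n < 3) stop("paired test needs n >= 3")
  d <- accA - accB
  if (stats::sd(d) < 1e-15) {
    if (abs(mean(d)) < 1e-15)
      return(list(t = 0, p = 1, df = n - 1))
    warning("zero-variance nonzero-mean differences; p reported as 0")
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1))
  }
  tt <- stats::t.test(accA, accB, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Write summary files for a set of evaluation reports
#'
#' Emits three CSV files into `outDir`:
#' * `summary.csv` - one row per (pipeline, classifier) with the mean
#'   accuracy and the across-subject standard deviation in brackets;
#' * `per_subject.csv` - long format, one row per report x subject;
#' * `pvalues.csv` - symmetric matrix of paired t-test p-values between the
#'   reports' accuracy vectors (unit diagonal), plus
#'   `pvalues_pairwise.csv` in long format with a Holm-corrected column.
#'
#' @param reports list of [LOSOReport-class] objects.
#' @param outDir output directory (created if missing).
#' @return invisibly, the paths of the written files.
#' @examples
#' fsyn <- plantedFeatureSet(4, 9, 2, 4, seed = 1)
#' rep1 <- runLoso(fsyn, "raw", classifierSpec("dt"))
#' writeReport(list(rep1), tempfile("report"))
#' @export
writeReport <- function(reports, outDir) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, methods::is, logical(1), "LOSOReport")))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(reports, function(r)
    paste(r@pipeline, r@classifier, sep = "/"), character(1))
  summary <- data.frame(
    pipeline = vapply(reports, function(r) r@pipeline, character(1)),
    classifier = vapply(reports, function(r) r@classifier, character(1)),
    mean_accuracy = vapply(reports, function(r) r@meanAccuracy, numeric(1)),
    sd_accuracy = vapply(reports, function(r) r@sdAccuracy, numeric(1)))
  summary$formatted <- sprintf("%.4f(%.2e)", summary$mean_accuracy,
                               summary$sd_accuracy)
  long <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(pipeline = r@pipeline, classifier = r@classifier,
               subject = names(r@accuracies),
               accuracy = unname(r@accuracies))
  }))
  k <- length(reports)
  pm <- matrix(1, k, k, dimnames = list(ids, ids))
  pairs <- NULL
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      res <- pairedT(reports[[i]]@accuracies, reports[[j]]@accuracies)
      pm[i, j] <- pm[j, i] <- res$p
      pairs <- rbind(pairs, data.frame(
        pipeline_A = ids[i], pipeline_B = ids[j],
        t = res$t, p = res$p, df = res$df))
    }
    pairs$p_holm <- stats::p.adjust(pairs$p, method = "holm")
  }
  paths <- file.path(outDir, c("summary.csv", "per_subject.csv",
                               "pvalues.csv", "pvalues_pairwise.csv"))
  utils::write.csv(summary, paths[1], row.names = FALSE)
  utils::write.csv(long, paths[2], row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(pm), pm, check.names = FALSE),
                   paths[3], row.names = FALSE)
  if (!is.null(pairs)) utils::write.csv(pairs, paths[4], row.names = FALSE)
  invisible(paths[file.exists(paths)])
}
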