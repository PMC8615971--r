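# Dynamical feature selection: recursive feature elimination re-run for
# every held-out subject on the NCA-selected, GFK-transformed features.

#' Recursive feature elimination ranking
#'
#' Iteratively fits the classifier, computes per-feature importance weights
#' and removes the lowest-weight feature (ties broken by removing the
#' larger column index first), until one feature remains. With n features
#' this costs the initial fit plus n - 1 refits. The first removed feature
#' has the lowest rank; the survivor the highest.
#'
#' @param X instances x features training matrix.
#' @param y integer class labels.
#' @param spec a [classifierSpec()].
#' @return a [FeatureRanking-class] without an accuracy curve.
#' @examples
#' X <- cbind(rep(0:2, 10) * 2, matrix(rnorm(60), 30, 2))
#' rfeRank(X, rep(0:2, 10), classifierSpec("dt"))@eliminationOrder
#' @export
rfeRank <- function(X, y, spec) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 1) stop("need at least one feature")
  remaining <- seq_len(n)
  order_ <- integer(0)
  while (length(remaining) > 1) {
    w <- featureWeights(spec, X[, remaining, drop = FALSE], y)
    ties <- which(w == min(w))
    victim <- remaining[max(ties)]
    order_ <- c(order_, victim)
    remaining <- setdiff(remaining, victim)
  }
  methods::new("FeatureRanking",
    eliminationOrder = c(order_, remaining),
    accuracyCurve = numeric(0), kStar = NA_integer_)
}

# Internal leave-one-subject-out accuracy for a fixed feature subset,
# pooled over all held-out predictions.
.losoAccuracy <- function(X, y, subjectIds, spec) {
  subjects <- unique(subjectIds)
  hits <- 0L
  for (s in subjects) {
    tr <- subjectIds != s
    fit <- fitClassifier(spec, X[tr, , drop = FALSE], y[tr])
    pred <- predictClassifier(fit, X[!tr, , drop = FALSE])
    hits <- hits + sum(pred == y[!tr])
  }
  hits / length(y)
}

#' Accuracy curve over ranked feature prefixes
#'
#' For each prefix size k = 1..n of the ranking (best-ranked first), trains
#' on the top-k features and scores by internal leave-one-subject-out over
#' the TRAINING subjects only; the held-out test subject of the enclosing
#' fold is never touched here, which keeps its labels out of the selection.
#' `kStar` is the smallest k attaining the maximal accuracy.
#'
#' @param ranking a [FeatureRanking-class] from [rfeRank()].
#' @param X,y training data the ranking was computed on.
#' @param subjectIds per-instance subject identifiers (>= 2 subjects).
#' @param spec a [classifierSpec()].
#' @return the ranking with `accuracyCurve` and `kStar` filled in.
#' @examples
#' X <- cbind(rep(0:2, 10) * 2, matrix(rnorm(60), 30, 2))
#' y <- rep(0:2, 10); subj <- rep(c("a", "b"), 15)
#' r <- rfeRank(X, y, classifierSpec("dt"))
#' accuracyCurve(r, X, y, subj, classifierSpec("dt"))@kStar
#' @export
accuracyCurve <- function(ranking, X, y, subjectIds, spec) {
  stopifnot(methods::is(ranking, "FeatureRanking"))
  X <- as.matrix(X)
  if (length(unique(subjectIds)) < 2)
    stop("accuracy curve needs >= 2 training subjects")
  ranked <- rev(ranking@eliminationOrder)   # best first
  curve <- vapply(seq_along(ranked), function(k) {
    .losoAccuracy(X[, ranked[seq_len(k)], drop = FALSE], y, subjectIds,
                  spec)
  }, numeric(1))
  methods::new("FeatureRanking",
    eliminationOrder = ranking@eliminationOrder,
    accuracyCurve = curve,
    kStar = as.integer(which.max(curve)))
}

# Single point where a fold reads the held-out subject's labels; kept as a
# named internal so tests can count accesses.
.heldOutLabels <- function(y, idx) y[idx]

#' Run the full dynamical feature selection over all held-out subjects
#'
#' For each held-out subject: features are z-scored with training-fold
#' statistics; the NCA is fitted on the training subjects and thresholded
#' to a feature subset; a geodesic flow kernel is fitted with the pooled
#' training subjects as source and the held-out subject as target (labels
#' unused); both domains are mapped through the kernel; recursive
#' elimination plus the internal leave-one-subject-out accuracy curve pick
#' the top-k* feature prefix; a final classifier trained on that prefix
#' scores the held-out subject once. A failing fold is recorded with an NA
#' accuracy and its error message; other folds continue.
#'
#' @param features an [EEGFeatureSet-class] with >= 3 subjects.
#' @param spec a [classifierSpec()]; per-fold seeds are derived from
#'   `seed`.
#' @param ncaCfg list of NCA options: `lambda` (fixed value, or `NULL` to
#'   select by [selectLambdaLoso()] on the training subjects), `grid`,
#'   `sigma`, `maxIter`, `thresholdFrac`, `minK`, `maxK`.
#' @param gfkCfg list of GFK options: `d` (fixed subspace dimension or
#'   `NULL` for SDM-based choice), `dMax`, `epsilon`.
#' @param useGfk `FALSE` replaces the kernel by the identity (ablation path
#'   reducing the pipeline to NCA + RFE).
#' @param seed integer; fold-level classifier seeds are derived from it.
#' @return a [DFSResult-class].
#' @examples
#' fsyn <- plantedFeatureSet(4, 9, 2, 4, seed = 1)
#' res <- runDfs(fsyn, classifierSpec("dt"),
#'   ncaCfg = list(lambda = 0.01, minK = 2, maxK = 4, maxIter = 10))
#' accuracies(res)
#' @export
runDfs <- function(features, spec = classifierSpec("rf"),
                   ncaCfg = list(), gfkCfg = list(), useGfk = TRUE,
                   seed = 1L) {
  stopifnot(methods::is(features, "EEGFeatureSet"))
  X <- featureValues(features)
  y <- classLabels(features)
  subj <- subjectIds(features)
  subjects <- unique(subj)
  if (length(subjects) < 3) stop("dynamical selection needs >= 3 subjects")
  cfg <- utils::modifyList(list(
    lambda = 0.01, grid = lambdaGrid(10), sigma = 1, maxIter = 50L,
    tol = 1e-6, thresholdFrac = 0.02, minK = 27L, maxK = 38L), ncaCfg)
  gcfg <- utils::modifyList(list(d = NULL, dMax = NULL, epsilon = 1e-3),
                            gfkCfg)
  rankings <- vector("list", length(subjects))
  masks <- vector("list", length(subjects))
  details <- vector("list", length(subjects))
  acc <- rep(NA_real_, length(subjects))
  for (f in seq_along(subjects)) {
    s <- subjects[f]
    foldSpec <- spec
    foldSpec$seed <- .subSeed(seed, f)
    res <- tryCatch({
      tr <- subj != s
      std <- .standardizer(X[tr, , drop = FALSE])
      Xtr <- std(X[tr, , drop = FALSE])
      Xte <- std(X[!tr, , drop = FALSE])
      ytr <- y[tr]
      lam <- cfg$lambda
      if (is.null(lam))
        lam <- selectLambdaLoso(X[tr, , drop = FALSE], ytr, subj[tr],
                                grid = cfg$grid, sigma = cfg$sigma,
                                maxIter = cfg$maxIter)$bestLambda
      nca <- fitNca(Xtr, ytr, lambda = lam, sigma = cfg$sigma,
                    maxIter = cfg$maxIter, tol = cfg$tol)
      nca <- selectFeatures(nca, cfg$thresholdFrac, cfg$minK, cfg$maxK)
      sel <- which(nca@selectedMask)
      XtrS <- Xtr[, sel, drop = FALSE]
      XteS <- Xte[, sel, drop = FALSE]
      if (useGfk) {
        gfk <- fitGfk(XtrS, XteS, d = gcfg$d, dMax = gcfg$dMax,
                      epsilon = gcfg$epsilon)
        G <- gfk@G
        dStar <- gfk@dStar
      } else {
        G <- diag(length(sel))
        dStar <- NA_integer_
      }
      XtrG <- transformFeatures(G, XtrS)
      XteG <- transformFeatures(G, XteS)
      ranking <- rfeRank(XtrG, ytr, foldSpec)
      ranking <- accuracyCurve(ranking, XtrG, ytr, subj[tr], foldSpec)
      top <- rev(ranking@eliminationOrder)[seq_len(ranking@kStar)]
      fit <- fitClassifier(foldSpec, XtrG[, top, drop = FALSE], ytr)
      pred <- predictClassifier(fit, XteG[, top, drop = FALSE])
      yte <- .heldOutLabels(y, which(!tr))
      list(ranking = ranking, sel = sel, selectedTop = sel[top],
           dStar = dStar, lambda = lam, accuracy = mean(pred == yte))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      details[[f]] <- list(error = conditionMessage(res))
      rankings[f] <- list(NULL)
      masks[f] <- list(NULL)
    } else {
      rankings[[f]] <- res$ranking
      masks[[f]] <- res$sel
      acc[f] <- res$accuracy
      details[[f]] <- res[c("selectedTop", "dStar", "lambda")]
    }
  }
  methods::new("DFSResult",
    subjects = as.character(subjects), rankings = rankings, masks = masks,
    accuracies = acc, details = details)
}
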