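# Classifier harness: a uniform fit / predict / feature-weight surface over
# the five evaluation classifiers plus a linear-margin ranker. Class labels
# are the integers 0/1/2 throughout.

#' Classifier specification for the evaluation harness
#'
#' Defaults follow the fixed hyper-parameter table used throughout the
#' evaluation: RF 50 estimators; AdaBoost 50 estimators, depth 24; GBDT 50
#' estimators, depth 16; XGBoost 50 estimators, depth 22; DT depth 10 with
#' at least 12 samples per leaf. `"multinom"` adds a multinomial-logit
#' linear-margin model usable as an elimination ranker.
#'
#' @param name one of `"rf"`, `"adaboost"`, `"gbdt"`, `"xgboost"`, `"dt"`,
#'   `"multinom"`.
#' @param nEstimators ensemble size (ignored for dt/multinom).
#' @param maxDepth tree depth cap.
#' @param minSamplesLeaf minimum samples per leaf (dt only).
#' @param seed integer seed for the stochastic learners.
#' @return a `ClassifierSpec` list.
#' @examples
#' classifierSpec("rf")
#' @export
classifierSpec <- function(name = c("rf", "adaboost", "gbdt", "xgboost",
                                    "dt", "multinom"),
                           nEstimators = NULL, maxDepth = NULL,
                           minSamplesLeaf = NULL, seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    rf = list(nEstimators = 50L, maxDepth = 0L, minSamplesLeaf = 1L),
    adaboost = list(nEstimators = 50L, maxDepth = 24L, minSamplesLeaf = 1L),
    gbdt = list(nEstimators = 50L, maxDepth = 16L, minSamplesLeaf = 1L),
    xgboost = list(nEstimators = 50L, maxDepth = 22L, minSamplesLeaf = 1L),
    dt = list(nEstimators = 1L, maxDepth = 10L, minSamplesLeaf = 12L),
    multinom = list(nEstimators = 1L, maxDepth = 0L, minSamplesLeaf = 1L))
  structure(list(
    name = name,
    nEstimators = as.integer(nEstimators %||% defaults$nEstimators),
    maxDepth = as.integer(maxDepth %||% defaults$maxDepth),
    minSamplesLeaf = as.integer(minSamplesLeaf %||% defaults$minSamplesLeaf),
    seed = as.integer(seed)), class = "ClassifierSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asDesign <- function(X) {
  X <- as.matrix(X)
  colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  X
}

# Multiclass AdaBoost (SAMME) over depth-limited rpart trees. Written here
# because no multiclass AdaBoost implementation ships with the stack.
.fitSamme <- function(X, y, nEstimators, maxDepth, seed) {
  set.seed(seed)
  n <- nrow(X)
  classes <- sort(unique(y))
  C <- length(classes)
  df <- data.frame(.y = factor(y, levels = classes), X)
  wts <- rep(1 / n, n)
  members <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = min(maxDepth, 30L), cp = 0,
                               xval = 0, minbucket = 1, minsplit = 2)
  for (m in seq_len(nEstimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = wts, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    miss <- pred != df$.y
    err <- sum(wts[miss]) / sum(wts)
    if (err <= 0) {        # perfect member dominates; stop with large alpha
      members[[m]] <- fit
      alphas[m] <- 10
      break
    }
    if (err >= 1 - 1 / C) break
    alpha <- log((1 - err) / err) + log(C - 1)
    members[[m]] <- fit
    alphas[m] <- alpha
    wts <- wts * exp(alpha * miss)
    wts <- wts / sum(wts)
  }
  if (!length(members)) {  # degenerate: fall back to a single tree
    members <- list(rpart::rpart(.y ~ ., data = df, method = "class",
                                 control = ctrl))
    alphas <- 1
  }
  list(members = members, alphas = alphas, classes = classes)
}

.predictSamme <- function(fit, X) {
  df <- data.frame(X)
  votes <- matrix(0, nrow(X), length(fit$classes))
  for (m in seq_along(fit$members)) {
    pred <- predict(fit$members[[m]], df, type = "class")
    votes <- votes + fit$alphas[m] *
      outer(as.integer(pred), seq_along(fit$classes), `==`)
  }
  fit$classes[max.col(votes, ties.method = "first")]
}

.xgbParams <- function(spec, nClass) {
  list(objective = "multi:softprob", num_class = nClass,
       max_depth = spec$maxDepth, nthread = 1, seed = spec$seed,
       eta = 0.3)
}

#' Fit a harness classifier
#'
#' @param spec a [classifierSpec()].
#' @param X instances x features matrix.
#' @param y integer class labels (0/1/2).
#' @return an opaque fit object for [predictClassifier()].
#' @examples
#' X <- matrix(rnorm(60), 30, 2); y <- rep(0:2, 10)
#' fit <- fitClassifier(classifierSpec("dt"), X, y)
#' @export
fitClassifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  if (length(unique(y)) < 2) stop("need >= 2 classes to fit a classifier")
  X <- .asDesign(X)
  classes <- sort(unique(y))
  fit <- switch(spec$name,
    rf = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = classes),
      num.trees = spec$nEstimators, importance = "impurity",
      seed = spec$seed, num.threads = 1),
    dt = rpart::rpart(
      .y ~ ., data = data.frame(.y = factor(y, levels = classes), X),
      method = "class",
      control = rpart::rpart.control(maxdepth = spec$maxDepth,
                                     minbucket = spec$minSamplesLeaf,
                                     minsplit = max(2L * spec$minSamplesLeaf,
                                                    2L),
                                     xval = 0, cp = 0)),
    adaboost = .fitSamme(X, y, spec$nEstimators, spec$maxDepth, spec$seed),
    gbdt = ,
    xgboost = xgboost::xgb.train(
      params = .xgbParams(spec, length(classes)),
      data = xgboost::xgb.DMatrix(X, label = match(y, classes) - 1),
      nrounds = spec$nEstimators, verbose = 0),
    multinom = nnet::multinom(
      .y ~ ., data = data.frame(.y = factor(y, levels = classes), X),
      trace = FALSE, maxit = 200, MaxNWts = 100000))
  structure(list(spec = spec, fit = fit, classes = classes, p = ncol(X)),
            class = "mfdfsClassifier")
}

#' Predict class labels from a harness classifier
#'
#' @param object a fit from [fitClassifier()].
#' @param X instances x features matrix (same feature order as at fit).
#' @return integer class labels.
#' @examples
#' X <- matrix(rnorm(60), 30, 2); y <- rep(0:2, 10)
#' fit <- fitClassifier(classifierSpec("dt"), X, y)
#' predictClassifier(fit, X)[1:5]
#' @export
predictClassifier <- function(object, X) {
  stopifnot(inherits(object, "mfdfsClassifier"))
  X <- .asDesign(X)
  spec <- object$spec
  classes <- object$classes
  switch(spec$name,
    rf = {
      pred <- predict(object$fit, data = as.data.frame(X),
                      num.threads = 1, seed = spec$seed)$predictions
      as.integer(as.character(pred))
    },
    dt = {
      pred <- predict(object$fit, data.frame(X), type = "class")
      as.integer(as.character(pred))
    },
    adaboost = .predictSamme(object$fit, X),
    gbdt = ,
    xgboost = {
      pr <- predict(object$fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(pr))
        pr <- matrix(pr, ncol = length(classes), byrow = TRUE)
      classes[max.col(pr, ties.method = "first")]
    },
    multinom = {
      pred <- predict(object$fit, data.frame(X), type = "class")
      as.integer(as.character(pred))
    })
}

#' Per-feature importance weights of a harness classifier
#'
#' Tree ensembles report mean impurity-decrease importance (summed over the
#' ensemble, AdaBoost members weighted by their vote weight); the decision
#' tree reports its impurity importance; the multinomial-logit model
#' reports the L2 norm of each feature's coefficients across classes.
#' Weights are non-negative, one per column of `X`; features a model never
#' uses get weight 0.
#'
#' @inheritParams fitClassifier
#' @return numeric vector of length `ncol(X)`.
#' @examples
#' X <- cbind(rep(0:2, 10) * 2, rnorm(30))
#' featureWeights(classifierSpec("dt"), X, rep(0:2, 10))
#' @export
featureWeights <- function(spec, X, y) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  X <- .asDesign(X)
  nm <- colnames(X)
  fill <- function(v) {
    out <- stats::setNames(rep(0, ncol(X)), nm)
    if (is.null(v) || !length(v)) return(out)
    v <- v[names(v) %in% nm]
    out[names(v)] <- v
    pmax(out, 0)
  }
  obj <- fitClassifier(spec, X, y)
  switch(spec$name,
    rf = fill(obj$fit$variable.importance),
    dt = fill(obj$fit$variable.importance),
    adaboost = {
      acc <- stats::setNames(rep(0, ncol(X)), nm)
      for (m in seq_along(obj$fit$members)) {
        vi <- obj$fit$members[[m]]$variable.importance
        if (!is.null(vi))
          acc[names(vi)] <- acc[names(vi)] + obj$fit$alphas[m] * vi
      }
      pmax(acc, 0)
    },
    gbdt = ,
    xgboost = {
      imp <- xgboost::xgb.importance(model = obj$fit)
      fill(stats::setNames(imp$Gain, imp$Feature))
    },
    multinom = {
      cf <- stats::coef(obj$fit)
      if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
      cf <- cf[, colnames(cf) != "(Intercept)", drop = FALSE]
      fill(stats::setNames(sqrt(colSums(cf^2)), colnames(cf)))
    },
    stop(sprintf(
      "classifier '%s' exposes no feature-weight interface", spec$name)))
}
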