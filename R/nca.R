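# Neighborhood component analysis with per-feature weights, an L1 base
# metric and an exponential kernel over the weighted distance:
#   D_w(i, j)  = sum_r w_r^2 |x_ir - x_jr|
#   p_ij       = exp(-D_ij / sigma) / sum_{j' != i} exp(-D_ij' / sigma)
#   p_i        = sum_{j != i, y_j = y_i} p_ij
#   F(w)       = mean_i p_i - lambda * sum_r w_r^2
# Softmax rows are stabilised by shifting each row of D by its off-diagonal
# minimum before exponentiation (the normalisation is shift-invariant).

# Per-feature absolute-difference matrices. For moderate problems they are
# cached; above ~4e7 cells they are recomputed on the fly.
.absDiffList <- function(X) {
  n <- nrow(X); p <- ncol(X)
  if (as.numeric(n) * n * p <= 4e7)
    lapply(seq_len(p), function(r) abs(outer(X[, r], X[, r], `-`)))
  else NULL
}

.ncaDistance <- function(X, w, A = NULL) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (r in seq_len(ncol(X))) {
    Ar <- if (is.null(A)) abs(outer(X[, r], X[, r], `-`)) else A[[r]]
    D <- D + w[r]^2 * Ar
  }
  D
}

# Reference-point probabilities p_ij from the distance matrix.
.ncaProbs <- function(D, sigma) {
  n <- nrow(D)
  diag(D) <- Inf
  m <- apply(D, 1, min)
  m[!is.finite(m)] <- 0
  K <- exp(-(D - m) / sigma)
  diag(K) <- 0
  P <- K / rowSums(K)
  P[!is.finite(P)] <- 0
  P
}

#' NCA objective and analytic gradient
#'
#' Evaluates the regularized expected leave-one-out accuracy of the
#' stochastic 1-nearest-neighbour rule, `F(w) = mean_i p_i - lambda *
#' sum_r w_r^2`, together with its exact gradient with respect to the
#' feature weights. See the package vignette for the model.
#'
#' @param w numeric weight vector (one entry per feature).
#' @param X instances x features matrix (standardized; the L1 base metric is
#'   scale-sensitive).
#' @param y integer class labels.
#' @param lambda L2 regularization strength (>= 0).
#' @param sigma kernel width (default 1).
#' @return list with elements `F` (scalar objective) and `gradient`.
#' @examples
#' X <- scale(matrix(rnorm(40), 10, 4)); y <- rep(0:1, 5)
#' ncaObjective(rep(1, 4), X, y, lambda = 0.1)$F
#' @export
ncaObjective <- function(w, X, y, lambda, sigma = 1) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 instances")
  A <- .absDiffList(X)
  same <- outer(y, y, `==`)
  diag(same) <- FALSE
  D <- .ncaDistance(X, w, A)
  P <- .ncaProbs(D, sigma)
  pi_ <- rowSums(P * same)
  Fval <- mean(pi_) - lambda * sum(w^2)
  grad <- numeric(ncol(X))
  for (r in seq_len(ncol(X))) {
    Ar <- if (is.null(A)) abs(outer(X[, r], X[, r], `-`)) else A[[r]]
    Er <- rowSums(P * Ar)          # E_j[ |dx_r| ]
    Sr <- rowSums(P * Ar * same)   # same-class part
    grad[r] <- (2 * w[r] / sigma) * mean(pi_ * Er - Sr) - 2 * lambda * w[r]
  }
  list(F = Fval, gradient = grad)
}

#' Fit the NCA weight vector by gradient ascent
#'
#' Batch gradient ascent with backtracking line search from `init`
#' (default: all weights 1), stopping when the objective improvement drops
#' below `tol` or after `maxIter` accepted steps. The returned weights are
#' reported as magnitudes (the metric uses `w^2`, so sign is irrelevant).
#'
#' @inheritParams ncaObjective
#' @param init initial weights (default all 1).
#' @param maxIter maximum accepted iterations.
#' @param tol convergence tolerance on the objective improvement.
#' @return an [NCAModel-class]; `@objectiveTrace` holds F per accepted step
#'   and is non-decreasing.
#' @examples
#' X <- scale(matrix(rnorm(90), 30, 3)); y <- rep(0:2, 10)
#' fitNca(X, y, lambda = 0.01, maxIter = 10)
#' @export
fitNca <- function(X, y, lambda = 0, sigma = 1, init = NULL,
                   maxIter = 100L, tol = 1e-6) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("need at least 2 classes to fit NCA")
  p <- ncol(X)
  w <- if (is.null(init)) rep(1, p) else init
  ob <- ncaObjective(w, X, y, lambda, sigma)
  trace <- ob$F
  step <- 1
  for (it in seq_len(maxIter)) {
    g <- ob$gradient
    gn2 <- sum(g^2)
    if (gn2 < 1e-20) break
    accepted <- FALSE
    while (step > 1e-12) {
      cand <- w + step * g
      obCand <- ncaObjective(cand, X, y, lambda, sigma)
      if (obCand$F >= ob$F + 1e-4 * step * gn2) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    delta <- obCand$F - ob$F
    w <- cand
    ob <- obCand
    trace <- c(trace, ob$F)
    step <- min(step * 2, 1e3)
    if (delta < tol) break
  }
  nms <- colnames(X)
  methods::new("NCAModel",
    w = abs(w), lambda = lambda, sigma = sigma,
    objectiveTrace = trace,
    selectedMask = rep(TRUE, p),
    featureNames = if (is.null(nms)) character(0) else nms)
}

# Expected-class prediction of the stochastic 1-NN rule for held-out rows:
# class posteriors are kernel-weighted training-label frequencies; the
# expected class is sum_c c * P(c | x).
.ncaPredict <- function(w, Xtrain, ytrain, Xtest, sigma = 1) {
  classes <- sort(unique(ytrain))
  D <- matrix(0, nrow(Xtest), nrow(Xtrain))
  for (r in seq_len(ncol(Xtrain)))
    D <- D + w[r]^2 * abs(outer(Xtest[, r], Xtrain[, r], `-`))
  m <- apply(D, 1, min)
  K <- exp(-(D - m) / sigma)
  P <- K / rowSums(K)
  probs <- vapply(classes, function(cl) rowSums(P[, ytrain == cl,
                                                  drop = FALSE]),
                  numeric(nrow(Xtest)))
  probs <- matrix(probs, nrow = nrow(Xtest))
  colnames(probs) <- as.character(classes)
  list(expected = as.numeric(probs %*% classes),
       hard = classes[max.col(probs, ties.method = "first")],
       probs = probs)
}

# z-scoring helper: parameters from the training block only.
.standardizer <- function(Xtrain) {
  mu <- colMeans(Xtrain)
  sd <- apply(Xtrain, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, sd, `/`)
}

#' Geometric grid of regularization strengths
#'
#' @param n number of grid points.
#' @param lo,hi grid range.
#' @return numeric vector, geometrically spaced.
#' @examples
#' lambdaGrid(5)
#' @export
lambdaGrid <- function(n = 20L, lo = 1e-4, hi = 1) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Select the NCA regularization strength by leave-one-subject-out loss
#'
#' For each candidate `lambda`, runs subject-wise leave-one-subject-out
#' validation: the NCA is fitted on all-but-one subject (features z-scored
#' with training-fold statistics) and the held-out subject's labels are
#' predicted with the stochastic 1-NN expected-class rule; the loss is the
#' mean squared error between expected and true integer-coded classes,
#' averaged over folds. The best `lambda` minimizes the mean loss, ties
#' going to the smaller value.
#'
#' @inheritParams ncaObjective
#' @param subjectIds per-instance subject identifiers (>= 3 subjects).
#' @param grid candidate lambda values (default [lambdaGrid()]).
#' @param maxIter,tol passed to [fitNca()].
#' @return list of class `LambdaSearchResult` with elements `grid`,
#'   `lossPerLambda`, `lossMatrix` (folds x lambdas), `bestLambda`,
#'   `nSelectedPerLambda`.
#' @examples
#' fsyn <- plantedFeatureSet(4, 9, 2, 4, seed = 1)
#' res <- selectLambdaLoso(featureValues(fsyn), classLabels(fsyn),
#'   subjectIds(fsyn), grid = c(0.001, 0.1), maxIter = 5)
#' res$bestLambda
#' @export
selectLambdaLoso <- function(X, y, subjectIds, grid = lambdaGrid(),
                             sigma = 1, maxIter = 50L, tol = 1e-6) {
  X <- as.matrix(X)
  subjects <- unique(subjectIds)
  if (length(subjects) < 3) stop("lambda selection needs >= 3 subjects")
  lossMatrix <- matrix(NA_real_, length(subjects), length(grid),
                       dimnames = list(subjects, NULL))
  nsel <- integer(length(grid))
  for (k in seq_along(grid)) {
    lam <- grid[k]
    foldLoss <- vapply(subjects, function(s) {
      tr <- subjectIds != s
      std <- .standardizer(X[tr, , drop = FALSE])
      fit <- fitNca(std(X[tr, , drop = FALSE]), y[tr], lambda = lam,
                    sigma = sigma, maxIter = maxIter, tol = tol)
      pred <- .ncaPredict(fit@w, std(X[tr, , drop = FALSE]), y[tr],
                          std(X[!tr, , drop = FALSE]), sigma)
      mean((pred$expected - y[!tr])^2)
    }, numeric(1))
    lossMatrix[, k] <- foldLoss
    stdAll <- .standardizer(X)
    fitAll <- fitNca(stdAll(X), y, lambda = lam, sigma = sigma,
                     maxIter = maxIter, tol = tol)
    nsel[k] <- sum(selectFeatures(fitAll)@selectedMask)
  }
  loss <- colMeans(lossMatrix)
  best <- grid[which.min(loss)]  # which.min takes the first = smallest tie
  structure(list(grid = grid, lossPerLambda = loss, lossMatrix = lossMatrix,
                 bestLambda = best, nSelectedPerLambda = nsel),
            class = "LambdaSearchResult")
}

#' Threshold-based feature selection from fitted NCA weights
#'
#' Selects features whose weight exceeds `thresholdFrac * max(w)`, then
#' clips the selected count into `[minK, maxK]` by taking the top-weight
#' features (ties broken by column order). The default 27-38 window mirrors
#' the size range the selection typically lands in on the reference
#' database layouts. When all weights are zero the top `minK` features by
#' gradient magnitude at the origin are kept (the gradient vanishes there,
#' so this reduces to column order) with a warning.
#'
#' @param model a fitted [NCAModel-class].
#' @param thresholdFrac fraction of the maximal weight (default 0.02).
#' @param minK,maxK bounds on the number of selected features.
#' @return the model with `@selectedMask` filled in.
#' @examples
#' m <- methods::new("NCAModel", w = c(1, .5, .001, 0), lambda = 0,
#'   sigma = 1, objectiveTrace = numeric(0), selectedMask = logical(0),
#'   featureNames = character(0))
#' which(selectFeatures(m, 0.02, minK = 1, maxK = 4)@selectedMask)
#' @export
selectFeatures <- function(model, thresholdFrac = 0.02,
                           minK = 27L, maxK = 38L) {
  w <- model@w
  p <- length(w)
  minK <- min(as.integer(minK), p)
  maxK <- min(as.integer(maxK), p)
  if (minK > maxK) stop("minK must not exceed maxK")
  if (max(w) <= 0) {
    warning("all NCA weights are zero; keeping the first minK features")
    ord <- seq_len(p)
  } else {
    ord <- order(-w, seq_len(p))
  }
  mask <- w > thresholdFrac * max(w)
  k <- sum(mask)
  if (k < minK || max(w) <= 0) {
    mask <- rep(FALSE, p)
    mask[ord[seq_len(minK)]] <- TRUE
  } else if (k > maxK) {
    mask <- rep(FALSE, p)
    mask[ord[seq_len(maxK)]] <- TRUE
  }
  methods::initialize(model, selectedMask = mask)
}
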