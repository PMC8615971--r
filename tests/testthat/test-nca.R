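test_that("zero weights give the uniform-kernel objective", {
  # n = 6 balanced over 3 classes: each point has 1 same-class neighbour of
  # 5, so mean p_i = 1/5 and the penalty vanishes at w = 0
  set.seed(1)
  X <- matrix(rnorm(30), 6, 5)
  y <- rep(0:2, each = 2)
  ob <- ncaObjective(rep(0, 5), X, y, lambda = 0.3)
  expect_equal(ob$F, 1 / 5, tolerance = 1e-12)
})

test_that("the objective decreases monotonically in lambda at fixed w", {
  set.seed(2)
  X <- scale(matrix(rnorm(60), 12, 5))
  y <- rep(0:2, 4)
  w <- runif(5, 0.5, 1.5)
  Fs <- vapply(c(0, 0.01, 0.1, 1, 10),
               function(l) ncaObjective(w, X, y, l)$F, numeric(1))
  expect_true(all(diff(Fs) < 0))
})

test_that("analytic gradient matches central finite differences", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- scale(matrix(rnorm(50), 10, 5))
    y <- sample(0:2, 10, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    w <- runif(5, 0.2, 2)
    ob <- ncaObjective(w, X, y, lambda = 0.05)
    h <- 1e-6
    num <- vapply(1:5, function(r) {
      wp <- w; wp[r] <- w[r] + h
      wm <- w; wm[r] <- w[r] - h
      (ncaObjective(wp, X, y, 0.05)$F -
         ncaObjective(wm, X, y, 0.05)$F) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - ob$gradient) / pmax(abs(num), 1e-8)), 1e-5)
  }
})

test_that("reference probabilities are a proper distribution", {
  set.seed(3)
  X <- scale(matrix(rnorm(200), 20, 10))
  y <- rep(0:2, length.out = 20)
  for (w in list(rep(0, 10), rep(1, 10), runif(10, 0, 3))) {
    P <- mfdfs:::.ncaProbs(mfdfs:::.ncaDistance(X, w), 1)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    pi_ <- rowSums(P * outer(y, y, `==`) * (1 - diag(20)))
    expect_true(all(pi_ >= 0 & pi_ <= 1))
  }
})

test_that("softmin stabilisation survives huge distances", {
  X <- scale(matrix(c(0, 1e6, -1e6, 2e6, 0, 1e6), 3, 2))
  w <- c(100, 100)
  P <- mfdfs:::.ncaProbs(mfdfs:::.ncaDistance(X, w), 1)
  expect_true(all(is.finite(P)))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
})

test_that("gradient ascent never decreases the objective", {
  fsyn <- plantedFeatureSet(3, 12, 2, 6, seed = 4)
  X <- scale(featureValues(fsyn))
  y <- classLabels(fsyn)
  m <- fitNca(X, y, lambda = 0.01, maxIter = 40)
  expect_true(all(diff(m@objectiveTrace) >= -1e-8))
  expect_gte(m@objectiveTrace[length(m@objectiveTrace)],
             m@objectiveTrace[1])
})

test_that("the informative feature earns the largest weight", {
  fsyn <- plantedFeatureSet(4, 15, 1, 4, effectSize = 2.5, shiftSd = 0.1,
                            seed = 6)
  X <- scale(featureValues(fsyn))
  m <- fitNca(X, classLabels(fsyn), lambda = 0.01, maxIter = 50)
  w <- ncaWeights(m)
  expect_gt(w["signal01"], max(w[-1]))
})

test_that("large lambda drives the weights toward zero", {
  fsyn <- plantedFeatureSet(3, 12, 2, 4, seed = 7)
  X <- scale(featureValues(fsyn))
  m <- fitNca(X, classLabels(fsyn), lambda = 50, maxIter = 60)
  expect_true(all(abs(m@w) < 0.01))
})

test_that("permuting feature columns permutes the weights identically", {
  fsyn <- plantedFeatureSet(3, 12, 2, 4, seed = 8)
  X <- scale(featureValues(fsyn))
  y <- classLabels(fsyn)
  perm <- c(3, 1, 6, 2, 5, 4)
  m1 <- fitNca(X, y, lambda = 0.02, maxIter = 25)
  m2 <- fitNca(X[, perm], y, lambda = 0.02, maxIter = 25)
  expect_equal(unname(m2@w), unname(m1@w[perm]), tolerance = 1e-10)
})

test_that("a common rescaling of standardized features keeps the mask", {
  fsyn <- plantedFeatureSet(3, 12, 2, 6, seed = 9)
  X <- featureValues(fsyn)
  y <- classLabels(fsyn)
  m1 <- selectFeatures(fitNca(scale(X), y, 0.01, maxIter = 20),
                       minK = 2, maxK = 5)
  m2 <- selectFeatures(fitNca(scale(7 * X), y, 0.01, maxIter = 20),
                       minK = 2, maxK = 5)
  expect_identical(m1@selectedMask, m2@selectedMask)
})

test_that("single-class input is rejected", {
  expect_error(fitNca(matrix(rnorm(20), 10, 2), rep(1L, 10), 0), "classes")
})

test_that("threshold selection and clipping follow the stated arithmetic", {
  m <- methods::new("NCAModel", w = c(1, 0.5, 0.001, 0), lambda = 0,
                    sigma = 1, objectiveTrace = numeric(0),
                    selectedMask = logical(0), featureNames = character(0))
  expect_identical(which(selectFeatures(m, 0.02, 1, 4)@selectedMask), 1:2)
  m2 <- methods::new("NCAModel", w = c(3, 2, 1), lambda = 0, sigma = 1,
                     objectiveTrace = numeric(0), selectedMask = logical(0),
                     featureNames = character(0))
  expect_identical(which(selectFeatures(m2, 0.02, 1, 2)@selectedMask), 1:2)
  m3 <- methods::new("NCAModel", w = rep(0, 5), lambda = 0, sigma = 1,
                     objectiveTrace = numeric(0), selectedMask = logical(0),
                     featureNames = character(0))
  expect_warning(sel <- selectFeatures(m3, 0.02, 2, 4), "zero")
  expect_identical(which(sel@selectedMask), 1:2)
})

test_that("lambda search honours the grid contract", {
  fsyn <- plantedFeatureSet(4, 9, 2, 4, seed = 10)
  X <- featureValues(fsyn); y <- classLabels(fsyn); s <- subjectIds(fsyn)
  one <- selectLambdaLoso(X, y, s, grid = 0.05, maxIter = 8)
  expect_equal(one$bestLambda, 0.05)
  expect_length(one$lossPerLambda, 1)
  expect_error(selectLambdaLoso(X[1:18, ], y[1:18], s[1:18],
                                grid = c(0.1, 1)), "3 subjects")
})

test_that("lambda selection prefers signal-preserving regularization", {
  fsyn <- plantedFeatureSet(5, 12, 3, 5, effectSize = 2, shiftSd = 0.2,
                            seed = 11)
  res <- selectLambdaLoso(featureValues(fsyn), classLabels(fsyn),
                          subjectIds(fsyn), grid = c(0.005, 0.05, 10),
                          maxIter = 25)
  expect_lt(min(res$lossPerLambda),
            res$lossPerLambda[length(res$lossPerLambda)])
  expect_true(res$bestLambda %in% c(0.005, 0.05))
})

test_that("pure-noise features leave the lambda loss flat", {
  fsyn <- plantedFeatureSet(6, 12, 0, 6, seed = 12)
  res <- selectLambdaLoso(featureValues(fsyn), classLabels(fsyn),
                          subjectIds(fsyn), grid = c(0.01, 0.1, 1),
                          maxIter = 15)
  # paired check across folds: no lambda significantly beats another
  best <- which.min(res$lossPerLambda)
  worst <- which.max(res$lossPerLambda)
  p <- stats::t.test(res$lossMatrix[, best], res$lossMatrix[, worst],
                     paired = TRUE)$p.value
  expect_gt(p, 0.01)
})

test_that("selection recovers planted features across seeds", {
  hits <- 0L
  for (seed in 1:10) {
    fsyn <- plantedFeatureSet(4, 12, 2, 8, effectSize = 2, shiftSd = 0.2,
                              seed = seed)
    m <- fitNca(scale(featureValues(fsyn)), classLabels(fsyn),
                lambda = 0.01, maxIter = 30)
    m <- selectFeatures(m, minK = 2, maxK = 5)
    if (all(1:2 %in% which(m@selectedMask))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
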