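test_that("PCA bases recover known subspaces deterministically", {
  # rank-1 data on a line in 3-D
  set.seed(1)
  dirv <- c(1, 2, 2) / 3
  X <- outer(rnorm(50), dirv)
  B <- pcaBasis(X, 1)
  expect_gt(abs(sum(B * dirv)), 1 - 1e-10)
  # full-rank reconstruction is exact at d = D
  X2 <- matrix(rnorm(500), 50, 10)
  B2 <- pcaBasis(X2, 10)
  Xc <- sweep(X2, 2, colMeans(X2))
  expect_lt(max(abs(Xc %*% B2 %*% t(B2) - Xc)), 1e-10)
  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(B2, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(pcaBasis(X2, 11), "d must lie")
})

test_that("principal angles agree with the projector-spectrum oracle", {
  # known construction: span(e1) vs span(cos(t) e1 + sin(t) e2)
  th <- 0.7
  P <- diag(4)[, 1, drop = FALSE]
  Q <- matrix(c(cos(th), sin(th), 0, 0), 4, 1)
  expect_equal(principalAngles(P, Q), th, tolerance = 1e-12)
  # random subspaces: cos^2(theta) equals the spectrum of the product of
  # the two orthogonal projectors (independent route)
  set.seed(2)
  for (i in 1:5) {
    P <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
    Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3]
    ang <- principalAngles(P, Q)
    ev <- sort(Re(eigen(P %*% t(P) %*% Q %*% t(Q))$values),
               decreasing = TRUE)[1:2]
    expect_equal(cos(ang)^2, pmax(ev, 0), tolerance = 1e-8)
  }
})

test_that("the subspace disagreement measure behaves at its extremes", {
  set.seed(3)
  XS <- matrix(rnorm(200), 50, 4)
  for (d in 1:2) expect_lt(sdm(XS, XS, d), 1e-6)
  # orthogonal dominant directions: source spans e1/e2, target e3/e4, the
  # pooled top-2 takes one strong axis from each, so both second angles
  # are 90 degrees and D(2) = 1
  mk <- function(cols, sds) {
    X <- matrix(rnorm(400, sd = 0.001), 100, 4)
    X[, cols] <- X[, cols] + cbind(rnorm(100, sd = sds[1]),
                                   rnorm(100, sd = sds[2]))
    X
  }
  XSo <- mk(1:2, c(10, 1)); XTo <- mk(3:4, c(10, 1))
  expect_gt(sdm(XSo, XTo, 2), 1 - 1e-3)
  ch <- chooseD(XSo, XTo, dMax = 2)
  expect_identical(ch$dStar, 2L)
})

test_that("dimension choice falls back to the curve maximum", {
  set.seed(4)
  XS <- matrix(rnorm(300), 75, 4)
  XT <- XS + matrix(rnorm(300, sd = 0.01), 75, 4)
  ch <- chooseD(XS, XT, dMax = 2)
  expect_true(ch$dStar %in% 1:2)
  expect_lt(max(ch$sdmCurve), 1 - 1e-3)
  expect_identical(ch$dStar,
                   as.integer(max(which(ch$sdmCurve == max(ch$sdmCurve)))))
  # epsilon = 1 qualifies every d; the minimum is taken
  expect_identical(chooseD(XS, XT, dMax = 2, epsilon = 1)$dStar, 1L)
})

test_that("subspace bases satisfy orthogonality invariants", {
  set.seed(5)
  m <- fitGfk(matrix(rnorm(600), 60, 10), matrix(rnorm(600), 60, 10), d = 3)
  b <- m@blocks
  expect_lt(max(abs(crossprod(b$PS) - diag(3))), 1e-10)
  expect_lt(max(abs(crossprod(b$PT) - diag(3))), 1e-10)
  expect_lt(max(abs(crossprod(b$RS, b$PS))), 1e-10)
  # cos^2 + sin^2 of the principal angles
  expect_lt(max(abs(cos(m@principalAngles)^2 + sin(m@principalAngles)^2
                    - 1)), 1e-8)
  expect_false(is.unsorted(m@principalAngles))
})

test_that("the geodesic hits both poles with orthonormal flow points", {
  set.seed(6)
  m <- fitGfk(matrix(rnorm(500), 50, 10), matrix(rnorm(500), 50, 10), d = 3)
  b <- m@blocks
  phi0 <- geodesicPoint(m, 0)
  phi1 <- geodesicPoint(m, 1)
  expect_lt(max(abs(phi0 %*% t(phi0) - b$PS %*% t(b$PS))), 1e-8)
  expect_lt(max(abs(phi1 %*% t(phi1) - b$PT %*% t(b$PT))), 1e-8)
  for (t in c(0.25, 0.5, 0.9))
    expect_lt(max(abs(crossprod(geodesicPoint(m, t)) - diag(3))), 1e-8)
  expect_error(geodesicPoint(m, 1.2), "\\[0, 1\\]")
})

test_that("closed-form kernel matches trapezoid quadrature of the flow", {
  set.seed(7)
  for (i in 1:5) {
    XS <- matrix(rnorm(400), 40, 10)
    XT <- matrix(rnorm(400), 40, 10)
    m <- fitGfk(XS, XT, d = 3)
    expect_lt(max(abs(gfkKernel(m) - quadratureKernel(m, 2000))), 1e-6)
  }
})

test_that("identical domains give the source projector as kernel", {
  set.seed(8)
  XS <- matrix(rnorm(400), 40, 10)
  m <- fitGfk(XS, XS, d = 3)
  PS <- m@blocks$PS
  expect_lt(max(abs(gfkKernel(m) - PS %*% t(PS))), 1e-8)
})

test_that("the kernel is symmetric positive semidefinite", {
  set.seed(9)
  m <- fitGfk(matrix(rnorm(600), 60, 10), matrix(rnorm(600), 60, 10), d = 4)
  G <- gfkKernel(m)
  expect_lt(max(abs(G - t(G))), 1e-10)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  for (i in 1:100) {
    x <- rnorm(10)
    expect_gte(drop(t(x) %*% G %*% x), -1e-8)
  }
})

test_that("feature transformation is the symmetric kernel map", {
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(transformFeatures(diag(3), X), X)
  expect_equal(transformFeatures(matrix(0, 3, 3), X), X * 0)
  set.seed(10)
  m <- fitGfk(matrix(rnorm(240), 40, 6), matrix(rnorm(240), 40, 6), d = 2)
  G <- gfkKernel(m)
  Z <- transformFeatures(G, X[, 1:3] %*% matrix(1, 3, 6) / 3 +
                              matrix(rnorm(60), 10, 6))
  # inner products through the kernel match the quadratic form
  Xr <- matrix(rnorm(60), 10, 6)
  Zr <- transformFeatures(G, Xr)
  expect_lt(max(abs(Zr %*% t(Xr) - Xr %*% G %*% t(Xr))), 1e-10)
  expect_error(transformFeatures(G, matrix(0, 2, 5)), "dimension")
})

test_that("growing the subject shift widens the principal angles", {
  shifts <- seq(0.05, 1.4, length.out = 10)
  meanAngle <- vapply(shifts, function(sh) {
    angles <- vapply(1:3, function(rep) {
      cfg <- synthConfig(nSubjects = 2, nTrialsPerSubject = 20,
                         trialSeconds = 2, fs = 128, nChannels = 4,
                         subjectShiftSd = sh, seed = 100 * rep)
      rec <- generateRecordings(cfg)
      seg <- segmentTrials(rec, 1)
      de <- featureValues(extractFeatures(seg, "DE"))
      # band variances (exp of twice the differential entropy, up to a
      # constant): the subject gain acts multiplicatively on these, so the
      # covariance rotates as the per-band scales drift apart
      bv <- exp(2 * de)
      X1 <- bv[seq_len(20), ]; X2 <- bv[21:40, ]
      mean(principalAngles(pcaBasis(X1, 3), pcaBasis(X2, 3)))
    }, numeric(1))
    mean(angles)
  }, numeric(1))
  expect_gt(stats::cor(shifts, meanAngle, method = "spearman"), 0.8)
})
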