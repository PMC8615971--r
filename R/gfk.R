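# Geodesic flow kernel domain adaptation. Source and target feature
# matrices are reduced to d-dimensional PCA subspaces; the kernel integrates
# the projector onto every subspace along the geodesic between them on the
# Grassmann manifold and has a closed form through the paired SVD of the
# source/complement projections of the target basis.

#' Top-d PCA basis of a data matrix
#'
#' Columns are the leading eigenvectors of the sample covariance of the
#' column-centered data, with a deterministic sign convention (the entry of
#' largest magnitude in each column is positive).
#'
#' @param X instances x dimensions matrix (centered internally by its own
#'   column means).
#' @param d number of components, `1 <= d <= min(D, n - 1)`.
#' @return D x d matrix with orthonormal columns.
#' @examples
#' B <- pcaBasis(matrix(rnorm(200), 50, 4), 2)
#' crossprod(B)
#' @export
pcaBasis <- function(X, d) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (d < 1 || d > min(D, n - 1))
    stop(sprintf("d must lie in [1, %d]", min(D, n - 1)))
  Xc <- sweep(X, 2, colMeans(X))
  V <- svd(Xc, nu = 0, nv = d)$v
  for (j in seq_len(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Principal angles between two subspaces
#'
#' Canonical angles from the singular values of `t(P) %*% Q`, clamped into
#' \[0, 1\] before `acos`; returned non-decreasing in \[0, pi/2\].
#'
#' @param P,Q matrices with orthonormal columns spanning the two subspaces.
#' @return numeric vector of `min(ncol(P), ncol(Q))` angles in radians.
#' @examples
#' principalAngles(diag(3)[, 1:2], diag(3)[, 2:3])
#' @export
principalAngles <- function(P, Q) {
  s <- svd(crossprod(P, Q), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, 0), 1))
}

#' Subspace disagreement measure
#'
#' `D(d) = 0.5 * (sin(alpha_d) + sin(beta_d))` where `alpha_d` (`beta_d`) is
#' the d-th principal angle between the source (target) PCA subspace and
#' the PCA subspace of the pooled data. Values near 1 indicate that d-th
#' directions of both domains are orthogonal to the pooled subspace.
#'
#' @param XS,XT source and target instances x dimensions matrices.
#' @param d candidate subspace dimension.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' XS <- matrix(rnorm(100), 25, 4); sdm(XS, XS, 2)
#' @export
sdm <- function(XS, XT, d) {
  PS <- pcaBasis(XS, d)
  PT <- pcaBasis(XT, d)
  PST <- pcaBasis(rbind(XS, XT), d)
  a <- principalAngles(PS, PST)[d]
  b <- principalAngles(PT, PST)[d]
  0.5 * (sin(a) + sin(b))
}

#' Choose the shared subspace dimension from the SDM curve
#'
#' Returns the smallest d whose disagreement measure reaches `1 - epsilon`
#' (exact equality with 1 is numerically unattainable). If no candidate
#' qualifies, the maximizer of the curve is returned, ties going to the
#' larger d (a larger subspace retains more of the fused features).
#'
#' @inheritParams sdm
#' @param dMax largest candidate dimension; default
#'   `min(floor(D / 2), nS - 1, nT - 1)` so the orthogonal complement can
#'   carry the flow.
#' @param epsilon tolerance below 1 (default 1e-3).
#' @return list with `dStar` (integer) and `sdmCurve` (numeric of length
#'   `dMax`).
#' @examples
#' XS <- matrix(rnorm(200), 50, 4); XT <- XS + 0.5
#' chooseD(XS, XT)$dStar
#' @export
chooseD <- function(XS, XT, dMax = NULL, epsilon = 1e-3) {
  D <- ncol(XS)
  if (is.null(dMax))
    dMax <- min(floor(D / 2), nrow(XS) - 1, nrow(XT) - 1)
  if (dMax < 1) stop("dMax must be >= 1")
  curve <- vapply(seq_len(dMax), function(d) sdm(XS, XT, d), numeric(1))
  hit <- which(curve >= 1 - epsilon)
  dStar <- if (length(hit)) min(hit) else max(which(curve == max(curve)))
  list(dStar = as.integer(dStar), sdmCurve = curve)
}

#' Fit a geodesic flow kernel between source and target domains
#'
#' Computes d-dimensional PCA bases `PS` and `PT` of the two domains (each
#' centered by its own mean), the orthogonal complement `RS` of `PS`, the
#' paired SVD blocks of `t(PS) %*% PT` and `t(RS) %*% PT`, the principal
#' angles, and the closed-form D x D kernel `G` (see [gfkKernel()]). The
#' subspace dimension is chosen by [chooseD()] unless given.
#'
#' @inheritParams chooseD
#' @param d subspace dimension; `NULL` to choose via the SDM curve.
#' @return a [GFKModel-class].
#' @examples
#' XS <- matrix(rnorm(300), 50, 6); XT <- matrix(rnorm(300), 50, 6)
#' fitGfk(XS, XT, d = 2)
#' @export
fitGfk <- function(XS, XT, d = NULL, dMax = NULL, epsilon = 1e-3) {
  XS <- as.matrix(XS); XT <- as.matrix(XT)
  D <- ncol(XS)
  if (ncol(XT) != D) stop("source and target must share the feature space")
  sdmCurve <- numeric(0)
  if (is.null(d)) {
    ch <- chooseD(XS, XT, dMax = dMax, epsilon = epsilon)
    d <- ch$dStar
    sdmCurve <- ch$sdmCurve
  }
  if (2 * d > D)
    stop("subspace dimension d must not exceed floor(D / 2)")
  PS <- pcaBasis(XS, d)
  PT <- pcaBasis(XT, d)
  RS <- qr.Q(qr(PS), complete = TRUE)[, (d + 1):D, drop = FALSE]
  sv <- svd(crossprod(PS, PT))
  U1 <- sv$u
  V <- sv$v
  cosTheta <- pmin(pmax(sv$d, 0), 1)
  theta <- acos(cosTheta)
  sinTheta <- pmin(pmax(sqrt(pmax(1 - cosTheta^2, 0)), 0), 1)
  # t(RS) %*% PT = -U2 Sigma t(V): recover U2 columnwise; angles ~ 0 make
  # the corresponding column irrelevant (its kernel weights vanish).
  B <- crossprod(RS, PT)
  M <- -B %*% V
  U2 <- matrix(0, D - d, d)
  for (j in seq_len(d))
    if (sinTheta[j] > 1e-12) U2[, j] <- M[, j] / sinTheta[j]
  G <- .gfkClosedForm(PS, RS, U1, U2, theta)
  methods::new("GFKModel",
    G = G, dStar = as.integer(d), sdmCurve = sdmCurve,
    principalAngles = theta,
    blocks = list(PS = PS, PT = PT, RS = RS, U1 = U1, U2 = U2, V = V))
}

# Closed-form kernel: with Omega = [PS U1, RS U2] and the integrals of
# cos/sin products over the geodesic parameter,
#   L1 = int_0^1 cos^2(t theta) dt  = 1/2 + sin(2 theta) / (4 theta)
#   L2 = -int_0^1 cos sin dt        = (cos(2 theta) - 1) / (4 theta)
#   L3 = int_0^1 sin^2(t theta) dt  = 1/2 - sin(2 theta) / (4 theta)
# small angles use 2nd-order Taylor limits (L1 -> 1, L2 -> -theta/2,
# L3 -> theta^2/3).
.gfkClosedForm <- function(PS, RS, U1, U2, theta) {
  small <- theta < 1e-6
  l1 <- ifelse(small, 1 - theta^2 / 3, 0.5 + sin(2 * theta) / (4 * theta))
  l2 <- ifelse(small, -theta / 2, (cos(2 * theta) - 1) / (4 * theta))
  l3 <- ifelse(small, theta^2 / 3, 0.5 - sin(2 * theta) / (4 * theta))
  d <- length(theta)
  Omega <- cbind(PS %*% U1, RS %*% U2)
  L <- rbind(cbind(diag(l1, d), diag(l2, d)),
             cbind(diag(l2, d), diag(l3, d)))
  G <- Omega %*% L %*% t(Omega)
  (G + t(G)) / 2
}

#' Point on the geodesic flow between the two subspaces
#'
#' `Phi(t) = PS U1 diag(cos(t theta)) - RS U2 diag(sin(t theta))`; `Phi(0)`
#' spans the source subspace and `Phi(1)` the target subspace, with
#' orthonormal columns for every t.
#'
#' @param model a fitted [GFKModel-class].
#' @param t position along the geodesic, in \[0, 1\].
#' @return D x d matrix.
#' @examples
#' XS <- matrix(rnorm(300), 50, 6); XT <- matrix(rnorm(300), 50, 6)
#' m <- fitGfk(XS, XT, d = 2)
#' crossprod(geodesicPoint(m, 0.5))
#' @export
geodesicPoint <- function(model, t) {
  stopifnot(methods::is(model, "GFKModel"))
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  b <- model@blocks
  th <- model@principalAngles
  b$PS %*% b$U1 %*% diag(cos(t * th), length(th)) -
    b$RS %*% b$U2 %*% diag(sin(t * th), length(th))
}

#' Map features through the geodesic flow kernel
#'
#' Applies the kernel as a linear transform, `(G %*% t(X))` transposed,
#' identically to source and target instances.
#'
#' @param G D x D kernel matrix (or a [GFKModel-class]).
#' @param X instances x D feature matrix.
#' @return transformed instances x D matrix.
#' @examples
#' transformFeatures(diag(3), matrix(1:6, 2, 3))
#' @export
transformFeatures <- function(G, X) {
  if (methods::is(G, "GFKModel")) G <- G@G
  X <- as.matrix(X)
  if (ncol(X) != nrow(G))
    stop("feature dimension does not match the kernel")
  out <- t(G %*% t(X))
  dimnames(out) <- dimnames(X)
  out
}
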