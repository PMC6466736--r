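#' Weighted centering of a response under a standardized structure matrix
#'
#' Computes the generalized-least-squares grand mean `mu_hat = 1' S^{-1} y`
#' (an unscaled projection because `S` is standardized so `1' S^{-1} 1 = 1`)
#' and the centered response `(I - J S^{-1}) y`, which has weighted mean zero.
#'
#' @param y response vector.
#' @param S standardized structure matrix (see [standardize_cov()]).
#' @return List with `mu` and `centered`.
#' @export
weighted_center <- function(y, S) {
  n <- length(y)
  if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
    stop("'S' must be an n x n matrix matching 'y'", call. = FALSE)
  Si <- .inv_pd(S, "S")
  if (abs(sum(Si) - 1) > 1e-8)
    stop("contract violation: 'S' is not standardized (1' S^-1 1 != 1); ",
         "use standardize_cov() first", call. = FALSE)
  mu <- sum(Si %*% y)
  list(mu = mu, centered = y - mu)
}

#' Whitening map that removes nuisance covariates
#'
#' Builds the oblique nuisance-removal projection
#' `C = I - X0 (X0' S^{-1} X0)^{-1} X0' S^{-1}` for a nuisance design `X0`
#' with `q` columns, forms the residual-space structure matrix `M = C S C'`,
#' and whitens it through its eigen-decomposition: with
#' `M = T Lambda T'` restricted to the `n - q` non-null eigenpairs,
#' `B = Lambda^{1/2} T' S^{-1}`. The resulting map satisfies `B S B' = I`
#' and `B X0 = 0` (both asserted numerically after construction). In the
#' univariate case (`X0` a column of ones, `S` standardized) `M` equals
#' `S - J` and `B` is the classical form `Lambda^{1/2} T' S^{-1}`.
#'
#' @param S structure matrix (symmetric positive definite; standardized when
#'   used inside a PB plan).
#' @param nuisance matrix of nuisance covariates (`n x q`, full column rank,
#'   `q <= n - 3`). For the univariate model this is the intercept column.
#' @return List with `C` (`n x n`), `B` (`(n-q) x n`), `vectors`
#'   (`T`, `n x (n-q)`) and `values` (`Lambda` diagonal, descending).
#' @export
whitening_map <- function(S, nuisance) {
  n <- nrow(S)
  nuisance <- as.matrix(nuisance)
  q <- ncol(nuisance)
  if (nrow(nuisance) != n)
    stop("'nuisance' row count does not match 'S'", call. = FALSE)
  if (qr(nuisance)$rank < q)
    stop("invalid design: nuisance covariates are rank deficient", call. = FALSE)
  if (n - q < 1L)
    stop("invalid design: no residual dimensions left", call. = FALSE)
  Si <- .inv_pd(S, "S")
  G <- crossprod(nuisance, Si)                      # X0' S^-1
  C <- diag(n) - nuisance %*% solve(G %*% nuisance, G)
  M <- .sym(C %*% S %*% t(C))
  ee <- eigen(M, symmetric = TRUE)
  keep <- ee$values > 1e-10 * max(ee$values)
  if (sum(!keep) != q)
    stop(sprintf(
      "conditioning error: expected a null space of dimension %d, found %d",
      q, sum(!keep)), call. = FALSE)
  Tm <- ee$vectors[, keep, drop = FALSE]
  lam <- ee$values[keep]
  B <- (sqrt(lam) * t(Tm)) %*% Si
  if (max(abs(B %*% S %*% t(B) - diag(n - q))) > 1e-8)
    stop("conditioning error: whitening identity B S B' = I failed", call. = FALSE)
  if (max(abs(B %*% nuisance)) > 1e-8 * max(abs(B)))
    stop("conditioning error: B does not annihilate the nuisance design",
         call. = FALSE)
  list(C = C, B = B, vectors = Tm, values = lam)
}

#' Orthogonal rotation aligning a vector with the constant direction
#'
#' Given the whitened covariate `z` of length `m`, constructs the unique
#' orthogonal matrix `P = I - Q Q' + Q Rot Q'` (from the QR decomposition of
#' `(1 | z)` with the positive-diagonal convention) such that
#' `P z = zeta * 1` with `zeta = ||z|| / sqrt(m)`, and `P u = u` for every
#' `u` orthogonal to `span(1, z)`. The cosine `xi = <z, 1> / (sqrt(m) ||z||)`
#' measures the angle between `z` and the constant vector. When `z` is
#' numerically collinear with `1`, `P` is the identity (positive multiple) or
#' the Householder reflection mapping `z/||z||` to `1/sqrt(m)` (negative
#' multiple).
#'
#' @param z non-zero numeric vector.
#' @return List with `P` (`m x m` orthogonal), `xi` and `zeta`.
#' @export
rotation_map <- function(z) {
  m <- length(z)
  .check_numeric(z, "z")
  nz <- sqrt(sum(z^2))
  if (nz <= .Machine$double.eps * m)
    stop("non-identifiable covariate: z is numerically zero ",
         "(the tested covariate lies in the nuisance span)", call. = FALSE)
  xi <- sum(z) / (sqrt(m) * nz)
  xi <- min(max(xi, -1), 1)
  zeta <- nz / sqrt(m)
  if (1 - abs(xi) < 1e-12) {
    if (xi > 0) {
      P <- diag(m)
    } else {
      v <- z / nz - rep(1 / sqrt(m), m)
      P <- diag(m) - 2 * tcrossprod(v) / sum(v^2)
    }
  } else {
    A <- cbind(rep(1, m), z)
    qrA <- qr(A)
    Q <- qr.Q(qrA)
    s <- sign(diag(qr.R(qrA)))
    Q <- sweep(Q, 2L, s, `*`)
    rt <- sqrt(1 - xi^2)
    Rot <- matrix(c(xi, -rt, rt, xi), 2L, 2L)
    P <- diag(m) - tcrossprod(Q) + Q %*% Rot %*% t(Q)
  }
  list(P = P, xi = xi, zeta = zeta)
}

#' Build a reusable PB transformation plan
#'
#' Composes the nuisance projection, whitening map and rotation for a fixed
#' design and covariance. The composite operator `PB` maps any response
#' sharing this design to `n - q` values that are uncorrelated with equal
#' variance `sigma2`; under the null their mean is zero and under the
#' alternative it is `zeta * beta`. Because the operators depend only on
#' `(X, k, cov)`, the plan is computed once and applied to any number of
#' response vectors (the efficiency mechanism exploited by [run_pbtest()]).
#'
#' @param X full design matrix (`n x p`), including the intercept column.
#' @param k column index of the covariate under test.
#' @param cov a `"pb_cov"` covariance specification.
#' @return Object of class `"pb_plan"`: list with `C`, `B`, `P`, `PB`, `z`,
#'   `xi`, `zeta`, eigenpairs `vectors`/`values`, and dimensions `n`, `q`,
#'   `k`.
#' @examples
#' cv <- as_pb_cov(diag(6))
#' pl <- pb_plan(cbind(1, rep(0:1, 3)), k = 2, cov = cv)
#' round(pl$zeta, 3)
#' @export
pb_plan <- function(X, k, cov) {
  if (!inherits(cov, "pb_cov"))
    stop("'cov' must be a pb_cov object (build_covariance()/as_pb_cov())",
         call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(cov$S) != n) stop("'cov' dimension does not match 'X'", call. = FALSE)
  if (length(k) != 1L || k < 1L || k > p)
    stop("'k' must index one column of 'X'", call. = FALSE)
  if (p < 2L)
    stop("the design must contain at least one nuisance column (intercept)",
         call. = FALSE)
  if (qr(X)$rank < p)
    stop("invalid design: 'X' is rank deficient", call. = FALSE)
  if (n - (p - 1L) < 3L)
    stop("sample too small: fewer than 3 residual dimensions after removing ",
         "the nuisance design", call. = FALSE)
  nuisance <- X[, -k, drop = FALSE]
  wm <- whitening_map(cov$S, nuisance)
  z <- drop(wm$B %*% X[, k])
  rot <- rotation_map(z)
  structure(list(C = wm$C, B = wm$B, P = rot$P, PB = rot$P %*% wm$B,
                 vectors = wm$vectors, values = wm$values,
                 z = z, xi = rot$xi, zeta = rot$zeta,
                 n = n, q = p - 1L, k = k, S = cov$S, sigma2 = cov$sigma2),
            class = "pb_plan")
}

#' @export
print.pb_plan <- function(x, ...) {
  cat(sprintf("PB transformation plan: n = %d, nuisance columns q = %d\n",
              x$n, x$q))
  cat(sprintf("  zeta = %.4g, xi = %.4g (angle cosine of z vs 1)\n",
              x$zeta, x$xi))
  invisible(x)
}

#' Apply a PB plan to one or many responses
#'
#' @param plan a `"pb_plan"` object.
#' @param y a response vector of length `n`, or a features-by-samples matrix
#'   with `n` columns (each row transformed independently).
#' @return Transformed response(s): a vector of length `n - q`, or a matrix
#'   with `n - q` columns.
#' @export
apply_plan <- function(plan, y) {
  if (!inherits(plan, "pb_plan")) stop("'plan' must be a pb_plan", call. = FALSE)
  if (is.matrix(y)) {
    if (ncol(y) != plan$n)
      stop("dimension mismatch: 'y' must have n columns", call. = FALSE)
    y %*% t(plan$PB)
  } else {
    .check_numeric(y, "y", len = plan$n)
    drop(plan$PB %*% y)
  }
}
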