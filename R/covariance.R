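#' Exchangeable block-correlation structure
#'
#' Describes the repeated-measures correlation model used throughout the
#' package: observations are grouped into blocks (subjects), observations in
#' the same block share a common correlation `rho`, and blocks are mutually
#' independent. Each within-block correlation matrix is the compound-symmetry
#' matrix `(1 - rho) I + rho J`, which is positive definite exactly when
#' `rho` lies in `(max_l -1/(n_l - 1), 1)`.
#'
#' @param subject per-observation block/subject identifier (coerced to factor;
#'   order of first appearance is preserved). Singleton blocks encode
#'   unmatched samples.
#' @param rho optional common within-block correlation. May be left `NULL`
#'   and estimated later with [estimate_rho()].
#' @return An object of class `"pb_blocks"`: a list with `labels` (factor),
#'   `sizes` (named integer vector of block sizes), `L` (number of blocks),
#'   `n` (total observations) and `rho`.
#' @seealso [build_covariance()], [estimate_rho()]
#' @examples
#' b <- exchangeable_blocks(rep(1:3, each = 2), rho = 0.5)
#' b$sizes
#' @export
exchangeable_blocks <- function(subject, rho = NULL) {
  if (length(subject) < 1L) stop("'subject' must be non-empty", call. = FALSE)
  labels <- factor(subject, levels = unique(subject))
  sizes <- table(labels)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  out <- structure(list(labels = labels, sizes = sizes,
                        L = length(sizes), n = length(labels), rho = NULL),
                   class = "pb_blocks")
  if (!is.null(rho)) {
    .check_numeric(rho, "rho", len = 1L)
    bounds <- .rho_bounds(sizes)
    if (rho <= bounds["lower"] || rho >= bounds["upper"]) {
      stop(sprintf(
        "rho = %g is outside the admissible interval (%.6g, 1) for these block sizes",
        rho, bounds["lower"]), call. = FALSE)
    }
    out$rho <- rho
  }
  out
}

#' @export
print.pb_blocks <- function(x, ...) {
  cat(sprintf("Exchangeable block structure: %d observations in %d blocks\n",
              x$n, x$L))
  cat(sprintf("  block sizes: %s\n",
              paste(names(table(x$sizes)), table(x$sizes), sep = "x",
                    collapse = ", ")))
  cat(sprintf("  rho: %s\n", if (is.null(x$rho)) "<not set>" else format(x$rho)))
  invisible(x)
}

#' Standardize a covariance matrix into scale and shape
#'
#' Splits a symmetric positive-definite covariance `Sigma` into a positive
#' scalar `sigma2` and a standardized structure matrix `S` with
#' `Sigma = sigma2 * S`, where the normalization is chosen so that
#' `1' S^{-1} 1 = 1`. Concretely `sigma2 = 1 / sum(solve(Sigma))`. This
#' normalization makes the weighted grand mean `1' S^{-1} y` an unscaled
#' projection, which the centering and whitening steps rely on.
#'
#' @param Sigma symmetric positive-definite matrix.
#' @return A list with components `sigma2` (scalar) and `S` (matrix).
#' @examples
#' standardize_cov(diag(2))  # sigma2 = 0.5, S = 2 I
#' @export
standardize_cov <- function(Sigma) {
  if (!is.matrix(Sigma) || nrow(Sigma) != ncol(Sigma))
    stop("'Sigma' must be a square matrix", call. = FALSE)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(abs(Sigma)))
    stop("decomposition error: 'Sigma' is not symmetric", call. = FALSE)
  Sigma <- .sym(Sigma)
  .check_pd(Sigma, "Sigma")
  Si <- .inv_pd(Sigma, "Sigma")
  sigma2 <- 1 / sum(Si)
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("decomposition error: sum of the inverse entries is not positive",
         call. = FALSE)
  list(sigma2 = sigma2, S = Sigma / sigma2)
}

#' Build a weighted block-exchangeable covariance
#'
#' Constructs `Sigma = W^{-1/2} Cor W^{-1/2}`, where `W = diag(w)` holds
#' per-observation inverse-variance weights (for RNA-seq, sequencing depth in
#' million reads) and `Cor` is the block-diagonal compound-symmetry
#' correlation implied by `blocks`. The result is then standardized via
#' [standardize_cov()]. Observations keep their original order; blocks need
#' not be contiguous.
#'
#' @param weights positive per-observation weights, length `n`.
#' @param blocks a `"pb_blocks"` object with `rho` set (see
#'   [exchangeable_blocks()]).
#' @return An object of class `"pb_cov"`: list with `Sigma`, `sigma2`, `S`,
#'   `weights`, `blocks` and `source = "built"`.
#' @examples
#' b <- exchangeable_blocks(c(1, 1), rho = 0.5)
#' build_covariance(c(4, 1), b)$Sigma
#' @export
build_covariance <- function(weights, blocks) {
  if (!inherits(blocks, "pb_blocks"))
    stop("'blocks' must be created by exchangeable_blocks()", call. = FALSE)
  if (is.null(blocks$rho))
    stop("'blocks' must carry a correlation; set rho in exchangeable_blocks()",
         call. = FALSE)
  n <- blocks$n
  .check_numeric(weights, "weights", len = n)
  if (any(weights <= 0))
    stop("invalid input: all weights must be strictly positive", call. = FALSE)
  same <- outer(blocks$labels, blocks$labels, `==`)
  Cor <- ifelse(same, blocks$rho, 0)
  diag(Cor) <- 1
  isw <- 1 / sqrt(weights)
  Sigma <- .sym(Cor * tcrossprod(isw))
  std <- standardize_cov(Sigma)
  structure(list(Sigma = Sigma, sigma2 = std$sigma2, S = std$S,
                 weights = weights, blocks = blocks, source = "built"),
            class = "pb_cov")
}

#' Wrap a known covariance matrix for use with the PB machinery
#'
#' @param Sigma symmetric positive-definite covariance matrix, supplied by the
#'   user rather than built from weights and a correlation model.
#' @return An object of class `"pb_cov"` with `source = "supplied"`.
#' @export
as_pb_cov <- function(Sigma) {
  std <- standardize_cov(Sigma)
  structure(list(Sigma = .sym(Sigma), sigma2 = std$sigma2, S = std$S,
                 weights = NULL, blocks = NULL, source = "supplied"),
            class = "pb_cov")
}

#' @export
print.pb_cov <- function(x, ...) {
  cat(sprintf("Covariance specification (%s): n = %d, sigma2 = %.6g\n",
              x$source, nrow(x$S), x$sigma2))
  if (!is.null(x$blocks))
    cat(sprintf("  blocks: %d, rho = %g\n", x$blocks$L, x$blocks$rho))
  invisible(x)
}

#' Moment estimator of the exchangeable within-block correlation
#'
#' Estimates the common within-block correlation from weighted least-squares
#' residuals. With `eps = sqrt(w) * (y - X beta_W)` (where `beta_W` is the
#' diagonal-weight LS fit of the full design), define
#' `SS1 = sum_l eps_l' eps_l` and `SS2 = sum_l (sum eps_l)^2`. The moment
#' estimator is
#' `rho_m = (SS2 - SS1) / ((1/n) sum_l n_l (n_l - 1) * SS1)`,
#' which for balanced designs coincides with the maximum-likelihood estimator
#' `(SS2 - SS1) / ((n_1 - 1) SS1)`. The small-sample downward bias is
#' corrected by the Olkin-Pratt factor
#' `rho_m * (1 + (1 - rho_m^2) / (2 (L - 3)))`, applied only when more than 3
#' blocks have at least two observations. The final estimate is clamped to
#' the interior of the positive-definite admissible interval.
#'
#' @param y response vector.
#' @param X design matrix of the full model (defaults to an intercept).
#' @param weights positive observation weights (default: equal).
#' @param blocks block structure: a `"pb_blocks"` object or a label vector.
#' @param correct apply the Olkin-Pratt correction (when `L_used > 3`).
#' @return An object of class `"pb_rho"`: list with `ss1`, `ss2`,
#'   `rho_moment`, `rho` (corrected and clamped), `L_used`, `corrected` and
#'   `bounds`.
#' @examples
#' y <- c(1, 1, -1, -1)
#' estimate_rho(y, blocks = rep(1:2, each = 2))$rho_moment  # 1
#' @export
estimate_rho <- function(y, X = NULL, weights = NULL, blocks, correct = TRUE) {
  n <- length(y)
  .check_numeric(y, "y")
  if (!inherits(blocks, "pb_blocks")) blocks <- exchangeable_blocks(blocks)
  if (blocks$n != n) stop("'blocks' length does not match 'y'", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("'X' row count does not match 'y'", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  .check_numeric(weights, "weights", len = n)
  if (any(weights <= 0)) stop("all weights must be positive", call. = FALSE)

  sizes <- blocks$sizes
  denom_coef <- sum(sizes * (sizes - 1)) / n
  if (denom_coef == 0)
    stop("estimation impossible: all blocks are singletons", call. = FALSE)

  sw <- sqrt(weights)
  fit <- stats::lm.wfit(x = X, y = y, w = weights)
  eps <- sw * fit$residuals
  ss1 <- sum(eps^2)
  if (ss1 <= 0)
    stop("degenerate residuals: SS1 is zero", call. = FALSE)
  block_sums <- tapply(eps, blocks$labels, sum)
  ss2 <- sum(block_sums^2)

  rho_m <- (ss2 - ss1) / (denom_coef * ss1)
  L_used <- sum(sizes >= 2L)
  corrected <- isTRUE(correct) && L_used > 3L
  rho <- if (corrected) rho_m * (1 + (1 - rho_m^2) / (2 * (L_used - 3))) else rho_m
  if (isTRUE(correct) && !corrected)
    warning("Olkin-Pratt correction skipped: fewer than 4 multi-observation blocks",
            call. = FALSE)
  bounds <- .rho_bounds(sizes)
  rho <- min(max(rho, bounds["lower"] + 1e-6), 1 - 1e-6)

  structure(list(ss1 = ss1, ss2 = ss2, rho_moment = rho_m, rho = unname(rho),
                 L_used = L_used, corrected = corrected, bounds = bounds),
            class = "pb_rho")
}

#' @export
print.pb_rho <- function(x, ...) {
  cat(sprintf("Within-block correlation estimate: rho = %.4f\n", x$rho))
  cat(sprintf("  moment estimate %.4f (SS1 = %.4g, SS2 = %.4g, L_used = %d%s)\n",
              x$rho_moment, x$ss1, x$ss2, x$L_used,
              if (x$corrected) ", Olkin-Pratt corrected" else ""))
  invisible(x)
}
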