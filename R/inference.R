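#' Effective degrees of freedom for the tested contrast
#'
#' Moment-matching (Kenward-Roger style) degrees of freedom for the single
#' contrast under the random-intercept + diagonal-weights covariance
#' `Sigma(theta) = sigma_eps^2 W^{-1} + sigma_gam^2 W^{-1/2} Z Z' W^{-1/2}`,
#' where `Z` is the block indicator matrix and the correlation maps to the
#' variance components through `rho = sigma_gam^2 / (sigma_gam^2 +
#' sigma_eps^2)`. The GLS variance of the contrast, its gradient in `theta`,
#' and the expected REML information of `theta` are combined in the
#' Satterthwaite first-two-moment match `df = 2 f^2 / (g' I^{-1} g)`, which
#' calibrates the scaled Wald statistic to an F(1, df) distribution.
#'
#' The approximation interpolates between the two classical limits: an
#' i.i.d. equal-weight two-group design of size `n` gives `df = n - 2`
#' (regression t-test), and a perfectly paired equal-weight design of `L`
#' pairs gives `df = L - 1` (paired t-test), for any within-pair correlation.
#' The df is non-increasing in `rho` for a fixed design, and never exceeds
#' `n - 1 - q`.
#'
#' @param X full design matrix (`n x p`, intercept included).
#' @param k column index of the tested covariate.
#' @param weights positive observation weights (default equal).
#' @param blocks block structure (a `"pb_blocks"` object or a label vector);
#'   `NULL` means all observations independent.
#' @param rho within-block correlation; taken from `blocks` when `NULL`
#'   there. With no multi-observation blocks or `rho = NULL` the model
#'   collapses to a single variance parameter and `df = n - p`.
#' @return The (possibly non-integer) degrees of freedom, with attribute
#'   `"fallback" = TRUE` when a singular information matrix forced the
#'   single-parameter Satterthwaite match (a warning is also raised).
#' @examples
#' X <- cbind(1, rep(0:1, each = 20))
#' effective_df(X, 2)                                  # 38
#' effective_df(X, 2, blocks = rep(1:20, 2), rho = .5) # 19
#' @export
effective_df <- function(X, k, weights = NULL, blocks = NULL, rho = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  .check_numeric(weights, "weights", len = n)
  if (!is.null(blocks) && !inherits(blocks, "pb_blocks"))
    blocks <- exchangeable_blocks(blocks)
  if (is.null(rho) && !is.null(blocks)) rho <- blocks$rho
  cap <- n - p                           # = n - 1 - q with q = p - 1

  two_par <- !is.null(blocks) && !is.null(rho) && any(blocks$sizes >= 2L)
  isw <- 1 / sqrt(weights)
  if (two_par) {
    same <- outer(blocks$labels, blocks$labels, `==`)
    Ve <- diag(1 / weights)
    Vg <- ifelse(same, 1, 0) * tcrossprod(isw)
    Sigma <- (1 - rho) * Ve + rho * Vg
    Vlist <- list(Ve, Vg)
  } else {
    Sigma <- diag(1 / weights)
    Vlist <- list(Sigma)
  }

  match_df <- function(Sigma, Vlist) {
    Si <- .inv_pd(Sigma, "Sigma(theta)")
    XtSi <- crossprod(X, Si)
    Phi <- solve(XtSi %*% X)
    f <- Phi[k, k]
    Pr <- Si - t(XtSi) %*% Phi %*% XtSi
    g <- vapply(Vlist, function(V)
      (Phi %*% XtSi %*% V %*% t(XtSi) %*% Phi)[k, k], numeric(1))
    PV <- lapply(Vlist, function(V) Pr %*% V)
    r <- length(Vlist)
    info <- matrix(0, r, r)
    for (i in seq_len(r)) for (j in i:r) {
      info[i, j] <- info[j, i] <- 0.5 * sum(PV[[i]] * t(PV[[j]]))
    }
    Cv <- solve(info)
    vf <- drop(crossprod(g, Cv %*% g))
    if (!is.finite(vf) || vf <= 0) stop("non-positive moment-match variance")
    2 * f^2 / vf
  }

  df <- tryCatch(match_df(Sigma, Vlist), error = function(e) NULL)
  fallback <- FALSE
  if (is.null(df) && length(Vlist) > 1L) {
    warning("information matrix not positive definite; ",
            "falling back to the single-parameter Satterthwaite match",
            call. = FALSE)
    fallback <- TRUE
    df <- match_df(Sigma, list(Sigma))
  }
  if (is.null(df)) stop("degrees-of-freedom approximation failed", call. = FALSE)
  df <- max(min(df, cap), 1)
  if (fallback) attr(df, "fallback") <- TRUE
  df
}

.new_pb_result <- function(method, estimate, statistic, df, p, stderr = NA_real_) {
  structure(list(method = method, estimate = estimate, statistic = statistic,
                 df = df, p.value = p, stderr = stderr),
            class = "pb_result")
}

#' @export
print.pb_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %.3f, p = %.4g\n",
              x$method, x$statistic, x$df, x$p.value))
  if (is.finite(x$estimate))
    cat(sprintf("  effect estimate = %.4g\n", x$estimate))
  invisible(x)
}

#' One-sample t-test on PB-transformed data
#'
#' Tests whether the common mean of the transformed values is zero. The
#' statistic is `t = mean(ytilde) * sqrt(m) / sd(ytilde)` referred to a
#' t-distribution with the supplied (possibly non-integer) degrees of
#' freedom; the effect estimate on the original scale is
#' `beta_hat = mean(ytilde) / zeta`.
#'
#' @param ytilde transformed response (length `m >= 3`).
#' @param zeta positive scale factor from the PB plan.
#' @param df degrees of freedom (see [effective_df()]); defaults to `m - 1`.
#' @return A `"pb_result"` with fields `method`, `estimate`, `statistic`,
#'   `df`, `p.value`, `stderr`.
#' @export
pb_ttest <- function(ytilde, zeta, df = length(ytilde) - 1) {
  m <- length(ytilde)
  if (m < 3L) stop("need at least 3 transformed values", call. = FALSE)
  if (!is.finite(zeta) || zeta <= 0) stop("'zeta' must be positive", call. = FALSE)
  s <- stats::sd(ytilde)
  if (s == 0) stop("degenerate data: transformed values are constant", call. = FALSE)
  mn <- mean(ytilde)
  tstat <- mn * sqrt(m) / s
  p <- 2 * stats::pt(-abs(tstat), df = df)
  .new_pb_result("pb_t", estimate = mn / zeta, statistic = tstat, df = df,
                 p = p, stderr = s / (sqrt(m) * zeta))
}

#' Wilcoxon signed-rank test on PB-transformed data
#'
#' Rank-based one-sample test for the transformed values. Zeros are dropped,
#' midranks are used for ties, and the signed-rank statistic
#' `V = sum of |ytilde| ranks over positive entries` is standardized by its
#' exact null moments (`E V = m(m+1)/4`,
#' `var V = m(m+1)(2m+1)/24 - sum(t^3 - t)/48` over tie groups). Following
#' the survey-sampling treatment of rank statistics under low effective
#' degrees of freedom, the standardized statistic is referred to a
#' t-distribution with the supplied adjusted df rather than a normal.
#'
#' @param ytilde transformed response (length `m >= 4`).
#' @param df degrees of freedom for the reference t-distribution; defaults to
#'   `m - 1`.
#' @param zeta optional scale factor; when given, a pseudo-estimate
#'   `median(ytilde) / zeta` of the effect is reported.
#' @return A `"pb_result"`.
#' @export
pb_wilcoxon <- function(ytilde, df = length(ytilde) - 1, zeta = NULL) {
  if (length(ytilde) < 4L) stop("need at least 4 transformed values", call. = FALSE)
  y <- ytilde[ytilde != 0]
  m <- length(y)
  if (m == 0L) stop("degenerate data: all transformed values are zero", call. = FALSE)
  r <- rank(abs(y))
  V <- sum(r[y > 0])
  EV <- m * (m + 1) / 4
  ties <- as.integer(table(r))
  varV <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  if (varV <= 0) stop("degenerate data: zero null variance of the rank statistic",
                      call. = FALSE)
  stat <- (V - EV) / sqrt(varV)
  p <- 2 * stats::pt(-abs(stat), df = df)
  est <- if (is.null(zeta)) NA_real_ else stats::median(ytilde) / zeta
  .new_pb_result("pb_wilcoxon", estimate = est, statistic = stat, df = df, p = p)
}

#' Spearman association test on whitened data
#'
#' Rank-correlation comparator for continuous covariates: correlates the
#' B-transformed response with the B-transformed covariate `z` and tests
#' `r * sqrt((m - 2) / (1 - r^2))` against a t-distribution. This uses only
#' the whitening half of the PB-transformation (no rotation), so it is a
#' comparator variant rather than a PB test proper.
#'
#' @param y2 whitened response `B y`.
#' @param z whitened covariate `B x`.
#' @param df degrees of freedom; default `m - 2`.
#' @return A `"pb_result"`.
#' @export
b_spearman <- function(y2, z, df = length(y2) - 2) {
  m <- length(y2)
  if (length(z) != m) stop("'y2' and 'z' lengths differ", call. = FALSE)
  if (m < 4L) stop("need at least 4 values", call. = FALSE)
  if (stats::sd(y2) == 0 || stats::sd(z) == 0)
    stop("degenerate data: constant input", call. = FALSE)
  r <- stats::cor(y2, z, method = "spearman")
  if (abs(r) >= 1) {
    stat <- sign(r) * Inf
    p <- .Machine$double.xmin        # reported as < machine minimum, never 0
  } else {
    stat <- r * sqrt((m - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(stat), df = df), .Machine$double.xmin)
  }
  .new_pb_result("b_spearman", estimate = r, statistic = stat, df = df, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validated wrapper over [stats::p.adjust()] with the step-up false
#' discovery rate procedure.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return Adjusted q-values (monotone, bounded by 1).
#' @export
bh_adjust <- function(pvals) {
  .check_numeric(pvals, "pvals")
  if (any(pvals < 0 | pvals > 1))
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}
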