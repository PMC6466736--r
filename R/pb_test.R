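#' PB-transformed hypothesis test
#'
#' Fits the regression-type testing problem `y = X beta + eps` with
#' correlated, heteroscedastic errors and tests a single covariate by
#' reducing the problem, through the PB-transformation, to a one-sample
#' location test on independent equal-variance values. The covariance is
#' either supplied (`Sigma`), or built from per-observation weights and an
#' exchangeable within-block correlation (`block`, `rho`); when `rho` is
#' unknown it is estimated from the data by the moment estimator with
#' Olkin-Pratt correction. Degrees of freedom are adjusted by a
#' Kenward-Roger-style moment match so that the test reproduces the
#' regression t-test for i.i.d. data and the paired t-test for perfectly
#' paired data.
#'
#' @param formula model formula, e.g. `y ~ group` or `y ~ age + group`.
#' @param data optional data frame holding the variables.
#' @param tested name of the covariate under test (default: the last
#'   non-intercept column of the model matrix). All other columns, including
#'   the intercept, are treated as nuisance and projected out.
#' @param block optional subject/block identifier (column name in `data` or a
#'   vector) encoding repeated measures; `NULL` means independent samples.
#' @param weights optional positive observation weights (column name or
#'   vector), inverse-variance scale.
#' @param rho optional known within-block correlation; estimated when `NULL`
#'   and `block` is given.
#' @param Sigma optional full covariance matrix, overriding
#'   `weights`/`block`/`rho`.
#' @param method `"t"` for the PB-transformed t-test, `"wilcoxon"` for the
#'   PB-transformed signed-rank test.
#' @param correct_rho apply the Olkin-Pratt correction when estimating `rho`.
#' @return Object of class `"pb_test"` with components `statistic`, `df`,
#'   `p.value`, `estimate` (the effect of the tested covariate), `stderr`,
#'   `zeta`, `xi`, `rho`, `rho_estimated`, `transformed` (the values the
#'   one-sample test was run on), `plan`, `method` and `call`. Methods:
#'   `print`, `summary`, `coef`, `confint`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rnorm(20), g = rep(0:1, 10), id = rep(1:10, each = 2))
#' pb_test(y ~ g, data = d, block = id, rho = 0.3)
#' @export
pb_test <- function(formula, data = NULL, tested = NULL, block = NULL,
                    weights = NULL, rho = NULL, Sigma = NULL,
                    method = c("t", "wilcoxon"), correct_rho = TRUE) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X)

  block <- eval(cl$block, data, environment(formula))
  weights <- eval(cl$weights, data, environment(formula))
  if (is.null(weights)) weights <- rep(1, n)
  .check_numeric(weights, "weights", len = n)

  nonint <- setdiff(colnames(X), "(Intercept)")
  if (length(nonint) == 0L)
    stop("the model must contain a covariate to test", call. = FALSE)
  if (is.null(tested)) tested <- nonint[length(nonint)]
  k <- match(tested, colnames(X))
  if (is.na(k))
    stop(sprintf("tested covariate '%s' is not a column of the model matrix (%s)",
                 tested, paste(colnames(X), collapse = ", ")), call. = FALSE)

  blocks <- if (!is.null(block)) exchangeable_blocks(block) else
    exchangeable_blocks(seq_len(n))

  rho_estimated <- FALSE
  rho_fit <- NULL
  if (is.null(Sigma)) {
    if (is.null(rho)) {
      if (any(blocks$sizes >= 2L)) {
        rho_fit <- estimate_rho(y, X, weights, blocks, correct = correct_rho)
        rho <- rho_fit$rho
        rho_estimated <- TRUE
      } else rho <- 0
    }
    blocks <- exchangeable_blocks(blocks$labels, rho = rho)
    cov <- build_covariance(weights, blocks)
    df <- effective_df(X, k, weights, blocks, rho)
  } else {
    cov <- as_pb_cov(Sigma)
    if (is.null(rho)) rho <- NA_real_
    df <- n - ncol(X)              # no variance-component decomposition known
  }

  plan <- pb_plan(X, k, cov)
  yt <- apply_plan(plan, y)
  res <- switch(method,
                t = pb_ttest(yt, plan$zeta, df),
                wilcoxon = pb_wilcoxon(yt, df, zeta = plan$zeta))

  structure(list(statistic = res$statistic, df = res$df, p.value = res$p.value,
                 estimate = stats::setNames(res$estimate, tested),
                 stderr = res$stderr, zeta = plan$zeta, xi = plan$xi,
                 rho = rho, rho_estimated = rho_estimated, rho_fit = rho_fit,
                 transformed = yt, plan = plan, cov = cov,
                 method = res$method, tested = tested, n = n, call = cl),
            class = "pb_test")
}

#' @export
print.pb_test <- function(x, digits = 4, ...) {
  lab <- switch(x$method, pb_t = "PB-transformed t-test",
                pb_wilcoxon = "PB-transformed Wilcoxon signed-rank test")
  cat("\n\t", lab, "\n\n", sep = "")
  cat(sprintf("tested covariate: %s  (n = %d, transformed length %d)\n",
              x$tested, x$n, length(x$transformed)))
  cat(sprintf("statistic = %s, df = %s, p-value = %s\n",
              format(x$statistic, digits = digits),
              format(x$df, digits = digits),
              format.pval(x$p.value, digits = digits)))
  if (is.finite(x$estimate))
    cat(sprintf("effect estimate: %s\n", format(x$estimate, digits = digits)))
  if (!is.na(x$rho))
    cat(sprintf("within-block correlation: %s%s\n",
                format(x$rho, digits = digits),
                if (x$rho_estimated) " (estimated)" else " (supplied)"))
  invisible(x)
}

#' @export
summary.pb_test <- function(object, ...) {
  structure(object, class = c("summary.pb_test", "pb_test"))
}

#' @export
print.summary.pb_test <- function(x, digits = 4, ...) {
  print.pb_test(x, digits = digits, ...)
  cat(sprintf("\ntransformation: zeta = %s, xi = %s, covariance %s\n",
              format(x$zeta, digits = digits), format(x$xi, digits = digits),
              x$cov$source))
  b <- x$cov$blocks
  if (!is.null(b))
    cat(sprintf("blocks: %d (%d with repeats)\n", b$L, sum(b$sizes >= 2L)))
  if (!is.null(x$rho_fit))
    cat(sprintf("rho estimate: moment %s, corrected %s (L_used = %d)\n",
                format(x$rho_fit$rho_moment, digits = digits),
                format(x$rho_fit$rho, digits = digits), x$rho_fit$L_used))
  if (is.finite(x$stderr)) {
    ci <- confint(x)
    cat(sprintf("95%% CI for the effect: [%s, %s]\n",
                format(ci[1], digits = digits), format(ci[2], digits = digits)))
  }
  invisible(x)
}

#' @export
coef.pb_test <- function(object, ...) object$estimate

#' @export
confint.pb_test <- function(object, parm, level = 0.95, ...) {
  if (!is.finite(object$stderr))
    stop("no standard error available for this method", call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, df = object$df)
  est <- unname(object$estimate)
  out <- c(est - q * object$stderr, est + q * object$stderr)
  names(out) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  out
}

#' @export
residuals.pb_test <- function(object, ...) {
  object$transformed - mean(object$transformed)
}

#' @export
plot.pb_test <- function(x, ...) {
  yt <- x$transformed
  graphics::hist(yt, breaks = "FD", freq = FALSE, col = "grey85",
                 main = "PB-transformed values",
                 xlab = expression(tilde(y)), ...)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(v = mean(yt), col = 2, lwd = 2)
  invisible(x)
}
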