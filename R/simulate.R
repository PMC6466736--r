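# symmetric unit-variance draws, rescaled by sd
.r_sym <- function(dist, n, sd = 1) {
  switch(dist,
         normal = stats::rnorm(n, 0, sd),
         double_exponential = {
           # Laplace with scale b = sd / sqrt(2) so that var = 2 b^2 = sd^2
           sample(c(-1, 1), n, replace = TRUE) * stats::rexp(n) * sd / sqrt(2)
         },
         logistic = stats::rlogis(n, 0, sd * sqrt(3) / pi),
         stop(sprintf(
           "invalid spec: '%s' is not a supported symmetric distribution", dist),
           call. = FALSE))
}

#' Simulation scenario specification
#'
#' Declares the study conditions for the simulation harness: a
#' group-comparison scenario (complete pairs with the group assignment made
#' within each pair) or a regression-type scenario (continuous
#' standard-normal covariate over blocks of repeated measures). Defaults
#' describe 20 subject blocks of size 2 (n = 40), weights drawn once per
#' replicate from Uniform(0.5, 2), intercept 1, unit noise scale, and an
#' effect size of 0.4 giving mid-range power.
#'
#' @param design `"paired"` (two-group comparison within pairs) or
#'   `"regression"` (continuous covariate).
#' @param L number of subject blocks of size 2.
#' @param rho true within-block correlation.
#' @param beta effect size under the alternative.
#' @param mu intercept (grand mean).
#' @param sigma2 noise scale multiplying the built covariance.
#' @param dist error distribution: `"normal"`, `"double_exponential"` or
#'   `"logistic"` (all symmetric, as the semiparametric construction
#'   requires).
#' @param weights `"uniform"` (Uniform(0.5, 2), redrawn each replicate) or
#'   `"equal"`.
#' @return Object of class `"pb_sim_spec"`.
#' @export
sim_spec <- function(design = c("paired", "regression"), L = 20, rho = 0.2,
                     beta = 0.4, mu = 1, sigma2 = 1,
                     dist = c("normal", "double_exponential", "logistic"),
                     weights = c("uniform", "equal")) {
  design <- match.arg(design)
  dist <- match.arg(dist)
  weights <- match.arg(weights)
  stopifnot(L >= 3, sigma2 >= 0)
  structure(list(design = design, L = L, n = 2L * L, rho = rho, beta = beta,
                 mu = mu, sigma2 = sigma2, dist = dist, weights = weights,
                 labels = rep(seq_len(L), each = 2L)),
            class = "pb_sim_spec")
}

.draw_weights <- function(spec) {
  switch(spec$weights,
         uniform = stats::runif(spec$n, 0.5, 2),
         equal = rep(1, spec$n))
}

.draw_x <- function(spec) {
  switch(spec$design,
         paired = rep(c(0, 1), spec$L),
         regression = stats::rnorm(spec$n))
}

#' Semiparametric generator with exact first and second moments
#'
#' Generates responses `Y = D (Ycheck + u 1) + (Ystar + v) 1` from `n - 1`
#' i.i.d. draws of a symmetric distribution plus one independent draw, where
#' `D = T Lambda^{1/2} P'` (so `D D' = S - J`), `u = zeta * beta` and
#' `v = mu + beta * (1' S^{-1} x)`. The construction guarantees
#' `E(Y) = mu 1 + beta x` and `cov(Y) = sigma2 * S` for every symmetric
#' generating density; with normal draws the output is exactly multivariate
#' normal. This inverts the PB-transformation, so it is the package's core
#' oracle: applying a PB plan to noise-free output returns `zeta * beta * 1`
#' exactly.
#'
#' @param x covariate vector (must not lie in the span of the intercept).
#' @param cov `"pb_cov"` covariance specification (provides the standardized
#'   `S`).
#' @param beta,mu effect size and intercept.
#' @param dist symmetric error distribution (see [sim_spec()]).
#' @param sigma2 noise variance multiplying the standardized `S`; the default
#'   `cov$sigma2` makes `cov(Y)` equal to the unstandardized `cov$Sigma`.
#' @param n_draws number of independent response vectors.
#' @param plan optional precomputed [pb_plan()] for `cbind(1, x)` under
#'   `cov` (avoids refactorizing when simulating repeatedly).
#' @return A vector of length `n` (`n_draws = 1`) or an `n x n_draws` matrix.
#' @export
simulate_response <- function(x, cov, beta = 0, mu = 0,
                              dist = "normal", sigma2 = NULL, n_draws = 1,
                              plan = NULL) {
  if (!inherits(cov, "pb_cov")) stop("'cov' must be a pb_cov", call. = FALSE)
  n <- nrow(cov$S)
  .check_numeric(x, "x", len = n)
  if (stats::sd(x) == 0)
    stop("'x' must not lie in the span of the intercept", call. = FALSE)
  if (is.null(sigma2)) sigma2 <- cov$sigma2
  if (sigma2 < 0) stop("'sigma2' must be non-negative", call. = FALSE)
  if (is.null(plan)) plan <- pb_plan(cbind(1, x), k = 2L, cov = cov)

  mean_vec <- mu + beta * x
  if (sigma2 == 0) {
    out <- matrix(mean_vec, n, n_draws)
    return(if (n_draws == 1L) drop(out) else out)
  }
  D <- sweep(plan$vectors, 2L, sqrt(plan$values), `*`) %*% t(plan$P)
  Si <- .inv_pd(cov$S, "S")
  u <- plan$zeta * beta
  v <- mu + beta * sum(Si %*% x)
  sdv <- sqrt(sigma2)
  Ycheck <- matrix(.r_sym(dist, (n - 1L) * n_draws, sdv), n - 1L, n_draws)
  Ystar <- .r_sym(dist, n_draws, sdv)
  out <- D %*% (Ycheck + u) + rep(1, n) %o% (Ystar + v)
  if (n_draws == 1L) drop(out) else out
}

# p-values of the classical comparator tests on one dataset
.classical_p <- function(method, y, x, labels) {
  switch(method,
         two_sample_t = stats::t.test(y[x == 1], y[x == 0],
                                      var.equal = TRUE)$p.value,
         welch_t = stats::t.test(y[x == 1], y[x == 0])$p.value,
         paired_t = {
           d <- tapply(y[x == 1], labels[x == 1], mean) -
             tapply(y[x == 0], labels[x == 0], mean)
           stats::t.test(d)$p.value
         },
         wilcoxon_rank_sum = stats::wilcox.test(y[x == 1], y[x == 0],
                                                exact = FALSE)$p.value,
         wilcoxon_signed_rank = {
           d <- tapply(y[x == 1], labels[x == 1], mean) -
             tapply(y[x == 0], labels[x == 0], mean)
           stats::wilcox.test(d, exact = FALSE)$p.value
         },
         spearman = stats::cor.test(x, y, method = "spearman",
                                    exact = FALSE)$p.value,
         stop(sprintf("unknown method label '%s'", method), call. = FALSE))
}

#' Classical comparator tests
#'
#' Two-sided p-values of the standard tests used as comparators by
#' [run_study()]: pooled and Welch two-sample t, paired t, Wilcoxon rank-sum
#' and signed-rank (for two-group designs with complete pairs), and the
#' Spearman correlation test (for continuous covariates).
#'
#' @param y response vector.
#' @param x covariate: a 0/1 group indicator or a continuous vector.
#' @param blocks block labels (needed by the paired tests).
#' @param methods which methods to run; defaults to all that are compatible
#'   with the design.
#' @return Named vector of p-values.
#' @export
classical_tests <- function(y, x, blocks = NULL, methods = NULL) {
  grouped <- all(x %in% c(0, 1))
  if (is.null(methods)) {
    methods <- if (grouped) {
      c("two_sample_t", "welch_t", "wilcoxon_rank_sum",
        if (!is.null(blocks)) c("paired_t", "wilcoxon_signed_rank"))
    } else "spearman"
  }
  needs_groups <- c("two_sample_t", "welch_t", "paired_t",
                    "wilcoxon_rank_sum", "wilcoxon_signed_rank")
  if (!grouped && any(methods %in% needs_groups))
    stop("incompatible design: group-comparison tests need a 0/1 covariate",
         call. = FALSE)
  if (any(methods %in% c("paired_t", "wilcoxon_signed_rank")) && is.null(blocks))
    stop("incompatible design: paired tests need block labels", call. = FALSE)
  labels <- if (is.null(blocks)) NULL else
    (if (inherits(blocks, "pb_blocks")) blocks$labels else blocks)
  vapply(methods, .classical_p, numeric(1), y = y, x = x, labels = labels)
}

.pb_methods <- c("pb_t_oracle", "pb_t_estimated", "pb_wilcoxon_oracle",
                 "pb_wilcoxon_estimated", "b_spearman")
.cls_methods <- c("two_sample_t", "paired_t", "welch_t", "wilcoxon_rank_sum",
                  "wilcoxon_signed_rank", "spearman")

# one dataset -> p-value for a single method
.method_p <- function(method, y, x, X, w, labels, ctx) {
  if (method %in% .cls_methods) return(.classical_p(method, y, x, labels))
  if (method %in% c("pb_t_oracle", "pb_wilcoxon_oracle")) {
    yt <- apply_plan(ctx$plan, y)
    return(if (method == "pb_t_oracle")
      pb_ttest(yt, ctx$plan$zeta, ctx$df)$p.value
      else pb_wilcoxon(yt, ctx$df)$p.value)
  }
  # estimation-based variants share one rho estimate per dataset
  est <- estimate_rho(y, X, w, labels)
  cov_e <- build_covariance(w, exchangeable_blocks(labels, rho = est$rho))
  plan_e <- pb_plan(X, 2L, cov_e)
  if (method == "b_spearman") {
    y2 <- drop(plan_e$B %*% y)
    return(b_spearman(y2, plan_e$z)$p.value)
  }
  df_e <- effective_df(X, 2L, w, labels, est$rho)
  yt <- apply_plan(plan_e, y)
  switch(method,
         pb_t_estimated = pb_ttest(yt, plan_e$zeta, df_e)$p.value,
         pb_wilcoxon_estimated = pb_wilcoxon(yt, df_e)$p.value,
         stop(sprintf("unknown method label '%s'", method), call. = FALSE))
}

#' Run a simulation study (type-I error, power, ROC/AUC)
#'
#' For each replicate, draws weights and the covariate, builds the oracle
#' covariance, and generates one null (`beta = 0`) and one alternative
#' dataset from the semiparametric generator; every requested method is run
#' on both. Reports the rejection rate at level `alpha` under the null
#' (type-I error) and the alternative (power), with the mean and SD across
#' `n_sets` contiguous replicate sets, and the ROC curve (threshold sweep
#' over pooled null/alternative p-values) with its trapezoid-rule AUC.
#' Fully reproducible from `seed`.
#'
#' @param spec a [sim_spec()] scenario.
#' @param methods character vector drawn from `pb_t_oracle`,
#'   `pb_t_estimated`, `pb_wilcoxon_oracle`, `pb_wilcoxon_estimated`,
#'   `b_spearman`, `two_sample_t`, `paired_t`, `welch_t`,
#'   `wilcoxon_rank_sum`, `wilcoxon_signed_rank`, `spearman`.
#' @param n_reps number of replicates.
#' @param alpha significance level.
#' @param seed integer seed (set once at entry).
#' @param n_sets number of replicate sets for the between-set SD.
#' @return Object of class `"pb_sim_result"`: list with `summary` (one row
#'   per method: type1, type1_sd, power, power_sd, auc), `roc` (per-method
#'   data frames of FPR/TPR), `auc_by_set`, `p_null`, `p_alt`, `spec`,
#'   `n_reps`, `alpha`.
#' @export
run_study <- function(spec, methods, n_reps = 200, alpha = 0.05, seed = NULL,
                      n_sets = 20) {
  stopifnot(inherits(spec, "pb_sim_spec"), n_reps >= 1)
  bad <- setdiff(methods, c(.pb_methods, .cls_methods))
  if (length(bad))
    stop(sprintf("unknown method label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  grouped_only <- c("two_sample_t", "welch_t", "paired_t",
                    "wilcoxon_rank_sum", "wilcoxon_signed_rank")
  if (spec$design == "regression" && any(methods %in% grouped_only))
    stop("incompatible design: group-comparison methods with a continuous covariate",
         call. = FALSE)
  if (spec$design == "paired" && any(methods %in% c("spearman", "b_spearman")))
    stop("incompatible design: correlation methods need a continuous covariate",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  labels <- spec$labels
  pn <- pa <- matrix(NA_real_, n_reps, length(methods),
                     dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    w <- .draw_weights(spec)
    x <- .draw_x(spec)
    X <- cbind(1, x)
    blocks <- exchangeable_blocks(labels, rho = spec$rho)
    cov <- build_covariance(w, blocks)
    ctx <- list(plan = pb_plan(X, 2L, cov),
                df = effective_df(X, 2L, w, blocks, spec$rho))
    s2 <- spec$sigma2 * cov$sigma2          # cov(Y) = sigma2 * Sigma
    y0 <- simulate_response(x, cov, beta = 0, mu = spec$mu, dist = spec$dist,
                            sigma2 = s2, plan = ctx$plan)
    y1 <- simulate_response(x, cov, beta = spec$beta, mu = spec$mu,
                            dist = spec$dist, sigma2 = s2, plan = ctx$plan)
    for (m in methods) {
      pn[r, m] <- .method_p(m, y0, x, X, w, labels, ctx)
      pa[r, m] <- .method_p(m, y1, x, X, w, labels, ctx)
    }
  }

  sets <- rep(seq_len(n_sets), length.out = n_reps)
  sets <- sets[order(sets)]                 # contiguous chunks
  roc <- list()
  auc_by_set <- matrix(NA_real_, n_sets, length(methods),
                       dimnames = list(NULL, methods))
  summ <- data.frame(method = methods, design = spec$design, rho = spec$rho,
                     dist = spec$dist, type1 = NA_real_, type1_sd = NA_real_,
                     power = NA_real_, power_sd = NA_real_, auc = NA_real_,
                     stringsAsFactors = FALSE)
  auc_of <- function(p0, p1) {
    thr <- sort(unique(c(0, p0, p1, 1)))
    fpr <- stats::ecdf(p0)(thr)
    tpr <- stats::ecdf(p1)(thr)
    fpr <- c(0, fpr); tpr <- c(0, tpr)
    sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  }
  for (j in seq_along(methods)) {
    m <- methods[j]
    t1_sets <- tapply(pn[, m] < alpha, sets, mean)
    pw_sets <- tapply(pa[, m] < alpha, sets, mean)
    summ$type1[j] <- mean(pn[, m] < alpha)
    summ$type1_sd[j] <- stats::sd(t1_sets)
    summ$power[j] <- mean(pa[, m] < alpha)
    summ$power_sd[j] <- stats::sd(pw_sets)
    summ$auc[j] <- auc_of(pn[, m], pa[, m])
    for (s in seq_len(n_sets)) {
      idx <- sets == s
      auc_by_set[s, j] <- auc_of(pn[idx, m], pa[idx, m])
    }
    thr <- sort(unique(c(0, pn[, m], pa[, m], 1)))
    roc[[m]] <- data.frame(threshold = thr,
                           fpr = stats::ecdf(pn[, m])(thr),
                           tpr = stats::ecdf(pa[, m])(thr))
  }
  structure(list(summary = summ, roc = roc, auc_by_set = auc_by_set,
                 p_null = pn, p_alt = pa, spec = spec, n_reps = n_reps,
                 alpha = alpha),
            class = "pb_sim_result")
}

#' @export
print.pb_sim_result <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation study: %s design, rho = %g, %s errors, %d replicates\n",
              x$spec$design, x$spec$rho, x$spec$dist, x$n_reps))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}
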