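# delimited reader: sep from extension (.csv -> comma, otherwise tab)
.read_delim_auto <- function(path, rownames = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (rownames) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
  }
  df
}

#' Read an expression study from delimited files
#'
#' Loads a features-by-samples expression matrix (assumed log-scale or
#' otherwise variance-stabilized) and a per-sample design table, validates
#' their alignment, and attaches observation weights. Weights can be given
#' directly (`weights_col` or `weights_path`) or derived from sequencing
#' depth (`depth_col`), in which case raw read counts are converted to the
#' million-reads scale: `w_i = depth_i * 1e-6`, so a sample with 23,800,000
#' reads gets weight 23.80.
#'
#' @param matrix_path TSV/CSV file: first column feature ids, one column per
#'   sample, numeric cells.
#' @param design_path TSV/CSV file: one row per sample, with a sample-id
#'   column named by `sample_col`.
#' @param covariate name of the design column under test (no missing values
#'   allowed).
#' @param nuisance character vector of nuisance design columns.
#' @param block optional design column with subject/block labels.
#' @param weights_col,depth_col optional design columns carrying weights or
#'   sequencing depths (in reads).
#' @param weights_path optional two-column file (sample, weight), passed
#'   through unchanged.
#' @param rho optional known within-block correlation.
#' @param sample_col name of the sample-id column in the design table.
#' @return Object of class `"pb_study"`: list with `matrix`, `design`,
#'   `covariate`, `nuisance`, `block`, `weights`, `rho`.
#' @export
read_study <- function(matrix_path, design_path, covariate,
                       nuisance = character(), block = NULL,
                       weights_col = NULL, depth_col = NULL,
                       weights_path = NULL, rho = NULL,
                       sample_col = "sample") {
  mat_df <- .read_delim_auto(matrix_path, rownames = TRUE)
  bad <- which(!vapply(mat_df, is.numeric, logical(1)))
  if (length(bad))
    stop(sprintf("parse error: non-numeric cells in matrix column(s) %s of '%s'",
                 paste(names(mat_df)[bad], collapse = ", "), matrix_path),
         call. = FALSE)
  mat <- as.matrix(mat_df)

  design <- .read_delim_auto(design_path)
  if (!sample_col %in% names(design))
    stop(sprintf("design table has no '%s' column", sample_col), call. = FALSE)
  ids <- as.character(design[[sample_col]])

  extra_m <- setdiff(colnames(mat), ids)
  extra_d <- setdiff(ids, colnames(mat))
  if (length(extra_m) || length(extra_d))
    stop(sprintf(
      "alignment error: samples only in matrix: [%s]; only in design: [%s]",
      paste(extra_m, collapse = ", "), paste(extra_d, collapse = ", ")),
      call. = FALSE)
  design <- design[match(colnames(mat), ids), , drop = FALSE]
  rownames(design) <- colnames(mat)

  for (col in c(covariate, nuisance, block)) {
    if (!col %in% names(design))
      stop(sprintf("design table has no '%s' column", col), call. = FALSE)
  }
  if (anyNA(design[[covariate]]))
    stop(sprintf("missing values in the tested covariate '%s'", covariate),
         call. = FALSE)

  n <- ncol(mat)
  w <- NULL
  if (!is.null(weights_path)) {
    wt <- .read_delim_auto(weights_path)
    wid <- as.character(wt[[1]])
    if (!setequal(wid, colnames(mat)))
      stop("alignment error: weights file samples do not match the matrix",
           call. = FALSE)
    w <- as.numeric(wt[[2]])[match(colnames(mat), wid)]
  } else if (!is.null(weights_col)) {
    w <- as.numeric(design[[weights_col]])
  } else if (!is.null(depth_col)) {
    w <- as.numeric(design[[depth_col]]) * 1e-6
  }
  if (!is.null(w)) {
    .check_numeric(w, "weights", len = n)
    if (any(w <= 0)) stop("invalid input: non-positive weight", call. = FALSE)
  }

  blk <- if (!is.null(block)) design[[block]] else NULL
  bl_sum <- if (is.null(blk)) "none" else {
    sz <- table(table(blk))
    paste(names(sz), sz, sep = "x", collapse = ", ")
  }
  message(sprintf("read_study: %d features x %d samples; blocks: %s; weights: %s",
                  nrow(mat), n, bl_sum,
                  if (is.null(w)) "equal" else "supplied"))
  structure(list(matrix = mat, design = design, covariate = covariate,
                 nuisance = nuisance, block = block, weights = w, rho = rho),
            class = "pb_study")
}

#' @export
print.pb_study <- function(x, ...) {
  cat(sprintf("Expression study: %d features x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  tested covariate: %s; nuisance: %s; blocks: %s\n",
              x$covariate,
              if (length(x$nuisance)) paste(x$nuisance, collapse = ", ") else "none",
              if (is.null(x$block)) "none" else x$block))
  invisible(x)
}

# design matrix and tested-column index for a study
.study_design <- function(study) {
  vars <- c(study$nuisance, study$covariate)
  fml <- stats::reformulate(vars)
  mm <- stats::model.matrix(fml, study$design)
  hits <- grep(paste0("^", study$covariate), colnames(mm))
  if (length(hits) != 1L)
    stop(sprintf(
      "tested covariate '%s' must map to exactly one model-matrix column (factors with >2 levels are not supported)",
      study$covariate), call. = FALSE)
  list(X = mm, k = hits)
}

#' Feature-by-feature PB-transformed testing
#'
#' Runs the PB-transformed test on every feature of an expression study. The
#' transformation plan is built exactly once per (design, covariance) pair
#' and all features are transformed by a single matrix product, so the
#' per-feature cost beyond the shared transform is O(n). When no correlation
#' is supplied and blocks are present, a single shared `rho` is obtained as
#' the median of the per-feature Olkin-Pratt-corrected moment estimates (the
#' across-feature IQR is logged). Features with zero variance are skipped
#' and logged.
#'
#' @param study a `"pb_study"` (see [read_study()], or build one directly).
#' @param method `"t"` or `"wilcoxon"`.
#' @param estimate_rho_if_missing estimate a shared correlation from the data
#'   when `study$rho` is `NULL` and blocks are present.
#' @param correct_rho apply the Olkin-Pratt correction to the per-feature
#'   estimates. Disabling it leaves the uncorrected moment estimate, which
#'   for balanced designs is the maximum-likelihood estimate (the plug-in
#'   value under which the PB t-test on perfectly paired equal-weight data
#'   reproduces the paired t-test exactly).
#' @return A `data.frame` (class `"pb_results"`) with columns `feature_id`,
#'   `beta_hat`, `statistic`, `df`, `p_value`, `fdr`, `method`; the `fdr`
#'   column is the Benjamini-Hochberg adjustment of `p_value` within the
#'   table. Attributes `rho` and `rho_estimated` record the correlation
#'   used.
#' @export
run_pbtest <- function(study, method = c("t", "wilcoxon"),
                       estimate_rho_if_missing = TRUE, correct_rho = TRUE) {
  method <- match.arg(method)
  if (!inherits(study, "pb_study")) stop("'study' must be a pb_study", call. = FALSE)
  Y <- study$matrix
  n <- ncol(Y)
  if (n < 6L) stop("need at least 6 samples", call. = FALSE)
  d <- .study_design(study)
  w <- if (is.null(study$weights)) rep(1, n) else study$weights
  labels <- if (is.null(study$block)) seq_len(n) else study$design[[study$block]]
  blocks0 <- exchangeable_blocks(labels)

  keep <- apply(Y, 1L, stats::sd) > 0
  if (any(!keep))
    message(sprintf("run_pbtest: skipped %d zero-variance feature(s)",
                    sum(!keep)))
  Yk <- Y[keep, , drop = FALSE]
  G <- nrow(Yk)
  if (G == 0L) stop("no features left after the variance filter", call. = FALSE)

  rho <- study$rho
  rho_estimated <- FALSE
  if (is.null(rho)) {
    if (estimate_rho_if_missing && any(blocks0$sizes >= 2L)) {
      rho_all <- .rho_per_feature(Yk, d$X, w, blocks0, correct = correct_rho)
      rho <- stats::median(rho_all)
      rho_estimated <- TRUE
      message(sprintf(
        "run_pbtest: shared rho = %.4f (median of %d per-feature estimates, IQR %.4f)",
        rho, length(rho_all), stats::IQR(rho_all)))
    } else rho <- 0
  }

  blocks <- exchangeable_blocks(labels, rho = rho)
  cov <- build_covariance(w, blocks)
  df <- effective_df(d$X, d$k, w, blocks, rho)
  plan <- pb_plan(d$X, d$k, cov)
  Yt <- apply_plan(plan, Yk)                         # G x (n - q)
  m <- ncol(Yt)

  if (method == "t") {
    means <- rowMeans(Yt)
    sds <- sqrt(pmax(rowSums((Yt - means)^2), 0) / (m - 1))
    ok <- sds > 0
    stat <- ifelse(ok, means * sqrt(m) / sds, NA_real_)
    pv <- 2 * stats::pt(-abs(stat), df = df)
    beta <- means / plan$zeta
    lab <- "pb_t"
  } else {
    res <- apply(Yt, 1L, function(yy) {
      r <- pb_wilcoxon(yy, df, zeta = plan$zeta)
      c(r$estimate, r$statistic, r$p.value)
    })
    beta <- res[1, ]; stat <- res[2, ]; pv <- res[3, ]
    lab <- "pb_wilcoxon"
  }

  out <- data.frame(feature_id = rownames(Yk), beta_hat = beta,
                    statistic = stat, df = df, p_value = pv,
                    fdr = bh_adjust(pv), method = lab,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rho") <- rho
  attr(out, "rho_estimated") <- rho_estimated
  class(out) <- c("pb_results", "data.frame")
  out
}

# vectorized per-feature moment estimates of rho (Olkin-Pratt corrected, clamped)
.rho_per_feature <- function(Y, X, w, blocks, correct = TRUE) {
  n <- ncol(Y)
  sw <- sqrt(w)
  Xs <- X * sw
  qx <- qr(Xs)
  Es <- qr.resid(qx, t(Y) * sw)                      # n x G weighted residuals
  ss1 <- colSums(Es^2)
  ss2 <- colSums(rowsum(Es, blocks$labels)^2)
  denom_coef <- sum(blocks$sizes * (blocks$sizes - 1)) / n
  if (denom_coef == 0)
    stop("estimation impossible: all blocks are singletons", call. = FALSE)
  ok <- ss1 > 0
  rho_m <- (ss2[ok] - ss1[ok]) / (denom_coef * ss1[ok])
  L_used <- sum(blocks$sizes >= 2L)
  rho <- if (correct && L_used > 3L)
    rho_m * (1 + (1 - rho_m^2) / (2 * (L_used - 3))) else rho_m
  bounds <- .rho_bounds(blocks$sizes)
  pmin(pmax(rho, bounds["lower"] + 1e-6), 1 - 1e-6)
}

#' Write a per-feature result table
#'
#' Tab-separated with a header row and the stable column order
#' `feature_id, beta_hat, statistic, df, p_value, fdr, method`; numeric
#' values keep full precision (15 significant digits), so a write/read
#' round trip preserves p-values to 1e-12.
#'
#' @param table a `"pb_results"` data frame from [run_pbtest()] (an empty
#'   table yields a header-only file).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path) {
  cols <- c("feature_id", "beta_hat", "statistic", "df", "p_value", "fdr",
            "method")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop(sprintf("result table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  ok <- tryCatch({
    utils::write.table(table[, cols, drop = FALSE], file = path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  invisible(path)
}
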