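# internal numerical helpers

# symmetry is enforced by averaging with the transpose before any decomposition
.sym <- function(A) (A + t(A)) / 2

# positive-definiteness check: smallest eigenvalue must exceed 1e-10 x largest
.check_pd <- function(A, name = "matrix", tol = 1e-10) {
  ev <- eigen(.sym(A), symmetric = TRUE, only.values = TRUE)$values
  if (ev[length(ev)] <= tol * max(ev)) {
    stop(sprintf("'%s' is not positive definite (min/max eigenvalue ratio %.3g)",
                 name, ev[length(ev)] / max(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

.inv_pd <- function(A, name = "matrix") {
  R <- tryCatch(chol(.sym(A)),
                error = function(e) stop(sprintf(
                  "decomposition of '%s' failed: not symmetric positive definite", name),
                  call. = FALSE))
  chol2inv(R)
}

.check_numeric <- function(x, name, len = NULL, finite = TRUE) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (!is.null(len) && length(x) != len)
    stop(sprintf("'%s' must have length %d (got %d)", name, len, length(x)),
         call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(TRUE)
}

# admissible interval for the exchangeable correlation, given block sizes:
# each block matrix (1-rho)I + rho J is PD iff rho > -1/(n_l - 1) and rho < 1
.rho_bounds <- function(sizes) {
  big <- sizes[sizes >= 2L]
  lower <- if (length(big)) max(-1 / (big - 1)) else -1
  c(lower = lower, upper = 1)
}
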