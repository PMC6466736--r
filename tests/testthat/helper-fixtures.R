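# random well-conditioned positive-definite matrix
rand_pd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + 0.5 * diag(n)
}

# random standardized structure matrix (1' S^-1 1 = 1)
rand_S <- function(n) standardize_cov(rand_pd(n))$S

# a paired two-group layout: L subject pairs, one observation per group
paired_design <- function(L) {
  list(labels = rep(seq_len(L), each = 2L),
       x = rep(c(0, 1), L),
       X = cbind(1, rep(c(0, 1), L)),
       n = 2L * L)
}

# covariance built from weights and an exchangeable block correlation
block_cov <- function(weights, labels, rho) {
  build_covariance(weights, exchangeable_blocks(labels, rho = rho))
}

# an in-memory expression study (features x samples), no files involved
make_study <- function(Y, design, covariate, nuisance = character(),
                       block = NULL, weights = NULL, rho = NULL) {
  structure(list(matrix = Y, design = design, covariate = covariate,
                 nuisance = nuisance, block = block, weights = weights,
                 rho = rho),
            class = "pb_study")
}
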