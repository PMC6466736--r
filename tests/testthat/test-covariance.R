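test_that("build_covariance reproduces the weighted compound-symmetry form", {
  # equal weights, zero correlation: identity
  cv <- block_cov(c(1, 1), c(1, 1), rho = 0)
  expect_equal(cv$Sigma, diag(2))

  # unequal weights scale rows and columns by 1/sqrt(w)
  cv <- block_cov(c(4, 1), c(1, 1), rho = 0.5)
  expect_equal(cv$Sigma, matrix(c(0.25, 0.25, 0.25, 1), 2), tolerance = 1e-12)

  # two independent blocks give a block-diagonal correlation
  cv <- block_cov(rep(1, 4), rep(1:2, each = 2), rho = 0.8)
  blk <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(cv$Sigma, rbind(cbind(blk, matrix(0, 2, 2)),
                               cbind(matrix(0, 2, 2), blk)))
  # Sigma = sigma2 * S always
  expect_equal(cv$Sigma, cv$sigma2 * cv$S, tolerance = 1e-12)
})

test_that("build_covariance rejects bad weights and out-of-range correlations", {
  expect_error(block_cov(c(1, -1), c(1, 1), rho = 0), "positive")
  expect_error(exchangeable_blocks(rep(1:2, each = 3), rho = -0.9),
               "admissible interval")
  expect_error(exchangeable_blocks(c(1, 1), rho = 1.2), "admissible interval")
})

test_that("standardization yields 1' S^-1 1 = 1 and splits scale from shape", {
  s <- standardize_cov(diag(2))
  expect_equal(s$sigma2, 0.5)
  expect_equal(s$S, 2 * diag(2))

  s <- standardize_cov(matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(s$sigma2, 0.75)
  expect_equal(s$S, (4 / 3) * matrix(c(1, 0.5, 0.5, 1), 2), tolerance = 1e-12)

  set.seed(42)
  for (n in c(3, 10, 40)) {
    Sigma <- rand_pd(n)
    s <- standardize_cov(Sigma)
    expect_lt(abs(sum(solve(s$S)) - 1), 1e-10)
    # scale invariance: standardize(c Sigma) = (c sigma2, same S)
    s2 <- standardize_cov(3.7 * Sigma)
    expect_equal(s2$sigma2, 3.7 * s$sigma2, tolerance = 1e-10)
    expect_equal(s2$S, s$S, tolerance = 1e-10)
    # idempotence: standardizing a standardized S leaves it unchanged
    s3 <- standardize_cov(s$S)
    expect_equal(s3$sigma2, 1, tolerance = 1e-10)
    expect_equal(s3$S, s$S, tolerance = 1e-10)
  }
  expect_error(standardize_cov(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(standardize_cov(matrix(1, 3, 3)), "positive definite")
})

test_that("moment estimator of rho matches hand computations", {
  # residuals (1,1,-1,-1), two blocks of 2: SS1 = 4, SS2 = 8, rho = 1
  suppressWarnings(
    est <- estimate_rho(c(1, 1, -1, -1), blocks = rep(1:2, each = 2),
                        correct = FALSE))
  expect_equal(est$ss1, 4)
  expect_equal(est$ss2, 8)
  expect_equal(est$rho_moment, 1)
  expect_lt(est$rho, 1)  # clamped inside the admissible interval

  # residuals (1,-1,1,-1): SS2 = 0, moment estimate -1, clamped above -1
  suppressWarnings(
    est <- estimate_rho(c(1, -1, 1, -1), blocks = rep(1:2, each = 2),
                        correct = FALSE))
  expect_equal(est$ss2, 0)
  expect_equal(est$rho_moment, -1)
  expect_equal(est$rho, -1 + 1e-6)
})

test_that("balanced designs reproduce the closed-form MLE identity", {
  set.seed(1)
  for (i in 1:20) {
    L <- sample(4:12, 1)
    n1 <- sample(2:4, 1)
    lab <- rep(seq_len(L), each = n1)
    y <- rnorm(L * n1) + 0.5 * rep(rnorm(L), each = n1)
    est <- suppressWarnings(estimate_rho(y, blocks = lab, correct = FALSE))
    mle <- (est$ss2 - est$ss1) / ((n1 - 1) * est$ss1)
    expect_equal(est$rho_moment, mle, tolerance = 1e-14)
  }
})

test_that("Olkin-Pratt correction and singleton-block bookkeeping behave", {
  set.seed(2)
  lab <- c(rep(1:5, each = 2), 6:9)   # 5 pairs plus 4 singletons
  y <- rnorm(14)
  est <- estimate_rho(y, blocks = lab)
  expect_equal(est$L_used, 5L)
  expect_true(est$corrected)
  expect_equal(est$rho,
               min(max(est$rho_moment * (1 + (1 - est$rho_moment^2) / (2 * 2)),
                       -1 + 1e-6), 1 - 1e-6))

  # too few multi-observation blocks: correction skipped with a warning
  expect_warning(est2 <- estimate_rho(rnorm(6), blocks = rep(1:3, each = 2)),
                 "Olkin-Pratt")
  expect_false(est2$corrected)

  expect_error(estimate_rho(rnorm(4), blocks = 1:4), "singleton")
  expect_error(suppressWarnings(
    estimate_rho(rep(0, 4), blocks = rep(1:2, each = 2))), "SS1")
})

test_that("the estimator recovers the generating correlation", {
  set.seed(3)
  L <- 100
  lab <- rep(seq_len(L), each = 2)
  x <- rep(c(0, 1), L)
  X <- cbind(1, x)
  rho <- 0.6
  w <- runif(2 * L, 0.5, 2)
  cv <- block_cov(w, lab, rho)
  est <- replicate(100, {
    y <- simulate_response(x, cv, beta = 0.3, mu = 1)
    estimate_rho(y, X, w, lab)$rho
  })
  expect_lt(abs(mean(est) - rho), 0.05)
})
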