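test_that("weighted centering removes the GLS grand mean", {
  wc <- weighted_center(c(3, 1), 2 * diag(2))
  expect_equal(wc$mu, 2)
  expect_equal(wc$centered, c(1, -1))

  set.seed(10)
  for (n in c(5, 20)) {
    S <- rand_S(n)
    y <- rnorm(n)
    wc <- weighted_center(y, S)
    # constant response is absorbed entirely by the mean
    expect_equal(weighted_center(rep(1, n), S)$centered, rep(0, n),
                 tolerance = 1e-10)
    # centered data have weighted mean zero
    expect_lt(abs(sum(solve(S) %*% wc$centered)), 1e-10)
  }
  expect_error(weighted_center(c(1, 2), diag(2)), "standardized")
})

test_that("whitening map solves the hand-computable univariate case", {
  wm <- whitening_map(2 * diag(2), matrix(1, 2, 1))
  # M = S - J has a single eigenpair (2, (1,-1)/sqrt(2)); B = +/-(1/2, -1/2)
  expect_equal(abs(drop(wm$B)), c(0.5, 0.5))
  expect_equal(drop(wm$B %*% (2 * diag(2)) %*% t(wm$B)), 1)
  expect_equal(drop(wm$B %*% c(1, 1)), 0)
  expect_equal(wm$values, 2)
})

test_that("whitening identities hold on randomized designs", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(6:40, 1)
    q <- sample(1:3, 1)
    S <- rand_S(n)
    X0 <- matrix(1, n, 1)
    if (q > 1) X0 <- cbind(X0, matrix(rnorm(n * (q - 1)), n))
    wm <- whitening_map(S, X0)
    m <- n - q
    expect_lt(max(abs(wm$B %*% S %*% t(wm$B) - diag(m))), 1e-8)
    expect_lt(max(abs(wm$B %*% X0)), 1e-8)
    expect_equal(length(wm$values), m)   # exactly q null directions removed
  }
  # scaling law: whitening c*S rescales B by 1/sqrt(c)
  S <- rand_S(8)
  b1 <- whitening_map(S, matrix(1, 8, 1))$B
  b2 <- whitening_map(4 * S, matrix(1, 8, 1))$B
  expect_equal(abs(b2), abs(b1) / 2, tolerance = 1e-8)

  expect_error(whitening_map(rand_S(6), cbind(1, rep(1, 6))), "rank deficient")
})

test_that("rotation map aligns z with the constant vector", {
  # already aligned: identity, zeta is the common value
  r <- rotation_map(rep(2.5, 7))
  expect_equal(r$P, diag(7))
  expect_equal(r$zeta, 2.5)
  expect_equal(r$xi, 1)

  # anti-aligned: Householder reflection still maps z to zeta * 1
  r <- rotation_map(rep(-3, 5))
  expect_equal(drop(r$P %*% rep(-3, 5)), rep(r$zeta, 5), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(r$P) - diag(5))), 1e-10)

  # explicit 2-d case
  r <- rotation_map(c(1, 0))
  expect_equal(r$zeta, 1 / sqrt(2))
  expect_equal(drop(r$P %*% c(1, 0)), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:10) {
    m <- sample(4:60, 1)
    z <- rnorm(m)
    r <- rotation_map(z)
    expect_lt(max(abs(crossprod(r$P) - diag(m))), 1e-10)
    expect_lt(max(abs(tcrossprod(r$P) - diag(m))), 1e-10)
    expect_equal(drop(r$P %*% z), rep(r$zeta, m), tolerance = 1e-10)
    # invariance on the orthogonal complement of span(1, z)
    u <- rnorm(m)
    A <- cbind(1, z)
    u <- u - A %*% solve(crossprod(A), crossprod(A, u))
    expect_lt(max(abs(r$P %*% u - u)), 1e-10)
  }
})

test_that("the PB plan composes correctly and is linear", {
  set.seed(13)
  n <- 12
  # identity-proportional structure, balanced two-group covariate: the scale
  # zeta is ||x_centered|| / sqrt(n (n-1)) = 1 / (2 sqrt(n-1))
  cv <- as_pb_cov(diag(n))
  x <- rep(0:1, each = n / 2)
  pl <- pb_plan(cbind(1, x), 2, cv)
  expect_equal(pl$zeta, 1 / (2 * sqrt(n - 1)), tolerance = 1e-10)

  # plan is linear in the response, and a pure-intercept response vanishes
  y <- rnorm(n)
  expect_equal(apply_plan(pl, 2 * y), 2 * apply_plan(pl, y), tolerance = 1e-12)
  expect_lt(max(abs(apply_plan(pl, rep(5, n)))), 1e-10)

  # noise-free signal maps to zeta * beta exactly
  w <- runif(n, 0.5, 2)
  lab <- rep(1:6, each = 2)
  cvb <- block_cov(w, lab, 0.4)
  xc <- rnorm(n)
  plb <- pb_plan(cbind(1, xc), 2, cvb)
  expect_equal(apply_plan(plb, 1.5 + 0.7 * xc), rep(plb$zeta * 0.7, n - 1),
               tolerance = 1e-10)

  # matrix responses transform row-wise
  Y <- rbind(y, y)
  expect_equal(apply_plan(plb, Y)[1, ], apply_plan(plb, y))

  # a covariate inside the nuisance span is rejected
  expect_error(pb_plan(cbind(1, rep(2, n)), 2, cvb), "rank deficient|nuisance")
})

test_that("transformed data are uncorrelated with equal variance", {
  set.seed(14)
  n <- 6
  w <- runif(n, 0.5, 2)
  lab <- rep(1:3, each = 2)
  cv <- block_cov(w, lab, 0.5)
  x <- rnorm(n)
  pl <- pb_plan(cbind(1, x), 2, cv)
  N <- 5000
  Y <- simulate_response(x, cv, beta = 0.5, mu = 1, n_draws = N)
  Yd <- apply_plan(pl, t(Y))           # draws in rows: N x (n-1)
  ctr <- sweep(Yd, 2, pl$zeta * 0.5)   # remove the common mean zeta*beta
  Sh <- crossprod(ctr) / N
  tgt <- cv$sigma2 * diag(n - 1)
  # entrywise three-standard-error band, SE estimated from the draws
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    se <- sd(ctr[, i] * ctr[, j]) / sqrt(N)
    expect_lt(abs(Sh[i, j] - tgt[i, j]), 3 * se + 1e-12)
  }
})

test_that("the test statistic is invariant to eigenvector sign flips", {
  set.seed(15)
  n <- 10
  w <- runif(n, 0.5, 2)
  cv <- block_cov(w, rep(1:5, each = 2), 0.3)
  x <- rnorm(n)
  y <- rnorm(n)
  pl <- pb_plan(cbind(1, x), 2, cv)
  t0 <- pb_ttest(apply_plan(pl, y), pl$zeta, df = 7)$statistic
  for (i in c(1, 4, n - 1)) {
    B2 <- pl$B
    B2[i, ] <- -B2[i, ]
    r2 <- rotation_map(drop(B2 %*% x))
    t1 <- pb_ttest(drop(r2$P %*% B2 %*% y), r2$zeta, df = 7)$statistic
    expect_equal(t1, t0, tolerance = 1e-10)
  }
})
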