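test_that("effective df reproduces the classical limits", {
  X <- cbind(1, rep(0:1, each = 20))
  expect_equal(effective_df(X, 2), 38)

  d <- paired_design(20)
  for (rho in c(0.1, 0.5, 0.9)) {
    expect_equal(effective_df(d$X, 2, blocks = d$labels, rho = rho), 19,
                 tolerance = 1e-8)
  }
})

test_that("effective df decreases with correlation and respects the cap", {
  set.seed(20)
  d <- paired_design(15)
  w <- runif(d$n, 0.5, 2)
  dfs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                function(r) effective_df(d$X, 2, w, d$labels, r), numeric(1))
  expect_true(all(diff(dfs) <= 1e-8))
  expect_true(all(dfs <= d$n - 2 + 1e-8))
  expect_true(all(dfs > 0))

  # partially paired design: more information than the pairs alone
  # (paired-only df would be 9) but less than fully independent data (28)
  lab <- c(rep(1:10, each = 2), 11:20)
  X <- cbind(1, c(rep(c(0, 1), 10), rep(0:1, each = 5)))
  df <- effective_df(X, 2, blocks = lab, rho = 0.5)
  expect_gt(df, 9)
  expect_lt(df, 28)
})

test_that("one-sample t on transformed data matches hand computations", {
  r <- pb_ttest(c(1, -1, 1, -1), zeta = 1, df = 3)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  r <- pb_ttest(c(2, 1, 3, 2), zeta = 1, df = 3)
  expect_equal(r$statistic, 4.899, tolerance = 1e-3)
  expect_equal(r$p.value, 0.0163, tolerance = 1e-2)
  expect_equal(r$estimate, 2)

  # scale equivariance: doubling the data doubles the estimate only
  r2 <- pb_ttest(2 * c(2, 1, 3, 2), zeta = 1, df = 3)
  expect_equal(r2$statistic, r$statistic)
  expect_equal(r2$p.value, r$p.value)
  expect_equal(r2$estimate, 2 * r$estimate)

  expect_error(pb_ttest(rep(1, 5), zeta = 1, df = 4), "degenerate|constant")
})

test_that("signed-rank statistic uses exact null moments with tie handling", {
  r <- pb_wilcoxon(c(1, -2, 3, -4), df = 3)
  expect_equal(r$statistic, (4 - 5) / sqrt(7.5), tolerance = 1e-10)

  # exactly symmetric data sit at the null center
  r <- pb_wilcoxon(c(2, -2, 5, -5), df = 3)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # zeros are dropped; ties get midranks and a variance correction
  r <- pb_wilcoxon(c(0, 1, 1, -1, 3), df = 4)
  m <- 4                       # one zero removed
  ev <- m * (m + 1) / 4
  vv <- m * (m + 1) * (2 * m + 1) / 24 - (3^3 - 3) / 48
  expect_equal(r$statistic, (2 + 2 + 4 - ev) / sqrt(vv), tolerance = 1e-12)

  expect_error(pb_wilcoxon(rep(0, 6), df = 5), "degenerate")
})

test_that("signed-rank p-values are invariant to strictly monotone odd maps", {
  set.seed(21)
  y <- rnorm(30)
  p0 <- pb_wilcoxon(y, df = 29)$p.value
  for (f in list(function(u) u^3, function(u) sign(u) * log1p(abs(u)),
                 function(u) 5 * u)) {
    expect_equal(pb_wilcoxon(f(y), df = 29)$p.value, p0, tolerance = 1e-12)
  }
})

test_that("signed-rank p-values are approximately uniform under the null", {
  set.seed(22)
  p <- replicate(400, pb_wilcoxon(rnorm(1000), df = 999)$p.value)
  # the signed-rank statistic is discrete, so ties across replicates are expected
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("whitened Spearman test behaves at its boundaries", {
  z <- 1:20
  r <- b_spearman(as.numeric(z), as.numeric(z))
  expect_equal(r$estimate, 1)
  expect_gt(r$p.value, 0)          # boundary handled, never exactly zero
  expect_lte(r$p.value, .Machine$double.xmin)

  set.seed(23)
  y2 <- sample(as.numeric(z))
  r <- b_spearman(y2, as.numeric(z), df = 18)
  expect_gt(r$p.value, 0.01)

  # exactly zero correlation gives statistic 0 and p = 1
  y0 <- c(1, 2, 3, 3, 2, 1)
  expect_equal(b_spearman(y0, as.numeric(1:6))$statistic, 0)
  expect_error(b_spearman(rep(1, 6), as.numeric(1:6)), "constant")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  q <- bh_adjust(runif(50))
  expect_true(all(q <= 1) && all(q >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
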