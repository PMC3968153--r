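test_that("profile ML matches the dense generic-optimizer oracle", {
  set.seed(21)
  g <- make_genotypes(12, 3, seed = 21)
  X <- cbind(rnorm(12), rbinom(12, 1, 0.5))
  y <- rnorm(12)
  w <- beta_maf_weights(g$variants$maf)$scaled
  pr <- null_projection(X)
  b <- spectral_basis_mixed(g, w, pr)
  C <- rv_kernel(g, w)$values
  for (l in c(0.1, 1, 10)) {
    d_pkg <- profile_ml_loglik(l, y, pr, b) - profile_ml_loglik(0, y, pr, b)
    d_orc <- dense_ml_loglik(l, y, X, C) - dense_ml_loglik(0, y, X, C)
    expect_equal(d_pkg, d_orc, tolerance = 1e-6)
  }
  # the null point itself: difference is exactly zero
  expect_equal(profile_ml_loglik(0, y, pr, b) - profile_ml_loglik(0, y, pr, b), 0)
})

test_that("profile REML matches the dense REML oracle", {
  set.seed(22)
  g <- make_genotypes(14, 3, seed = 22)
  X <- matrix(rnorm(14), 14, 1)
  y <- rnorm(14)
  w <- beta_maf_weights(g$variants$maf)$scaled
  pr <- null_projection(X)
  b <- spectral_basis_mixed(g, w, pr)
  C <- rv_kernel(g, w)$values
  for (l in c(0.5, 2)) {
    d_pkg <- profile_reml_loglik(l, y, pr, b) - profile_reml_loglik(0, y, pr, b)
    d_orc <- dense_reml_loglik(l, y, X, C) - dense_reml_loglik(0, y, X, C)
    expect_equal(d_pkg, d_orc, tolerance = 1e-6)
  }
})

test_that("maximisation recovers boundary and interior optima", {
  # monotone decreasing objective -> boundary solution (0, 0)
  res <- maximize_over_lambda(function(l) -l)
  expect_equal(res$lambda_hat, 0)
  expect_equal(res$statistic, 0)
  # constructed quadratic in log(lambda) with analytic peak at lambda*
  lstar <- 3.7
  f <- function(l) {
    ifelse(l == 0, -10, 5 - (log(l) - log(lstar))^2)
  }
  res2 <- maximize_over_lambda(f)
  expect_equal(res2$lambda_hat, lstar, tolerance = 1e-3)
  expect_equal(res2$statistic, 2 * (5 - f(0)), tolerance = 1e-6)
  # grid maximum at the upper endpoint raises the boundary warning
  expect_warning(res3 <- maximize_over_lambda(function(l) l), "boundary")
  expect_gt(res3$statistic, 0)
})

test_that("observed (Re)LRT statistics match dense maximisation on 20 instances", {
  set.seed(23)
  devs <- replicate(20, {
    n <- sample(15:30, 1)
    m <- sample(2:5, 1)
    g <- make_genotypes(n, m)
    X <- matrix(rnorm(n), n, 1)
    # half the instances carry real signal so lambda_hat > 0 is exercised
    beta_g <- if (runif(1) < 0.5) rnorm(m, sd = 0.6) else rep(0, m)
    y <- drop(g$counts %*% beta_g) + rnorm(n)
    w <- beta_maf_weights(g$variants$maf)$scaled
    pr <- null_projection(X)
    b <- spectral_basis_mixed(g, w, pr)
    C <- rv_kernel(g, w)$values
    s_ml <- maximize_over_lambda(function(l) profile_ml_loglik(l, y, pr, b))$statistic
    s_reml <- maximize_over_lambda(function(l) profile_reml_loglik(l, y, pr, b))$statistic
    c(abs(s_ml - dense_lrt_stat(y, X, C, reml = FALSE)),
      abs(s_reml - dense_lrt_stat(y, X, C, reml = TRUE)))
  })
  expect_lt(max(devs), 1e-5)
})

test_that("a zero covariance leaves the profile likelihood flat", {
  # basis whose spectrum is numerically zero relative to nothing: use a
  # single variant with weight ~ 0 so C ~ 0
  g <- make_genotypes(10, 1, maf = 0.3, seed = 30)
  pr <- null_projection(n = 10)
  b <- spectral_basis_mixed(g, 1e-12, pr)
  y <- rnorm(10)
  vals <- profile_ml_loglik(c(0, 0.5, 5), y, pr, b)
  expect_lt(max(vals) - min(vals), 1e-8)
})
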