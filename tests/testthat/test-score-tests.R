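test_that("Q reduces to burden and SKAT forms at the rho extremes", {
  g <- make_genotypes(30, 4, seed = 50)
  w <- beta_maf_weights(g$variants$maf)$scaled
  set.seed(51)
  y <- rnorm(30)
  pr <- null_projection(cbind(rnorm(30)))
  r <- project_null(pr, y)
  s <- drop(crossprod(g$counts, r)) * w
  expect_equal(skat_q(y, pr, g, w, rho = 1), sum(s)^2, tolerance = 1e-12)
  expect_equal(skat_q(y, pr, g, w, rho = 0), sum(s^2), tolerance = 1e-12)
  # intermediate rho interpolates the two quadratic forms
  expect_equal(skat_q(y, pr, g, w, rho = 0.3),
               0.7 * sum(s^2) + 0.3 * sum(s)^2, tolerance = 1e-12)
  expect_error(skat_q(y, pr, g, w, rho = 1.2), "rho")
})

test_that("Q agrees with hand matrix arithmetic on a 4 x 2 toy", {
  G <- rbind(c(0, 1), c(1, 0), c(2, 1), c(0, 0))
  dimnames(G) <- list(paste0("s", 1:4), c("v1", "v2"))
  g <- genotype_matrix(G)
  y <- c(1.2, -0.4, 0.9, -0.1)
  pr <- null_projection(n = 4)
  w <- c(0.8, 0.5)
  r <- y - mean(y)
  R <- matrix(0.25, 2, 2); diag(R) <- 1
  q_hand <- drop(t(r) %*% G %*% diag(w) %*% R %*% diag(w) %*% t(G) %*% r)
  expect_equal(skat_q(y, pr, g, w, rho = 0.25), q_hand, tolerance = 1e-12)
})

test_that("null mixture weights have the right rank structure", {
  g <- make_genotypes(40, 3, seed = 52)
  w <- beta_maf_weights(g$variants$maf)$scaled
  set.seed(53)
  y <- rnorm(40)
  pr <- null_projection(n = 40)
  s0 <- sum(project_null(pr, y)^2) / (40 - 1)
  # m = 1: the single weight is sigma0^2 w^2 g'P0g
  g1 <- subset_variants(g, 1)
  cs1 <- null_mixture_weights(y, pr, g1, w[1])
  gv <- g1$counts[, 1]
  expect_equal(cs1, s0 * w[1]^2 * drop(crossprod(gv, pr$P0 %*% gv)),
               tolerance = 1e-8)
  # rho = 1 collapses to a single nonzero eigenvalue
  cs_burden <- null_mixture_weights(y, pr, g, w, rho = 1)
  expect_length(cs_burden, 1L)
  cs_skat <- null_mixture_weights(y, pr, g, w, rho = 0)
  expect_length(cs_skat, 3L)
})

test_that("Q under fresh Gaussian nulls follows the fitted chi-square mixture", {
  n <- 50
  g <- make_genotypes(n, 4, seed = 54)
  w <- beta_maf_weights(g$variants$maf)$scaled
  pr <- null_projection(n = n)
  set.seed(55)
  y0 <- rnorm(n)
  cs <- null_mixture_weights(y0, pr, g, w, rho = 0, sigma0_sq = 1)
  qs <- replicate(5000, skat_q(rnorm(n), pr, g, w, rho = 0))
  ref <- colSums(cs * matrix(rchisq(5000 * length(cs), 1), length(cs)))
  ks <- suppressWarnings(stats::ks.test(qs, ref))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("mixture p-values match chi-square closed forms", {
  # single weight c: upper tail of c * chisq_1
  for (m in c("davies", "liu")) {
    expect_equal(mixture_chisq_pvalue(3.2, 2, method = m),
                 pchisq(3.2 / 2, 1, lower.tail = FALSE), tolerance = 1e-6)
  }
  # equal weights c * (1,1,1): c * chisq_3, Davies to 1e-8
  expect_equal(mixture_chisq_pvalue(7.5, c(1.5, 1.5, 1.5), method = "davies"),
               pchisq(7.5 / 1.5, 3, lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(mixture_chisq_pvalue(0, c(1, 2)), 1)
  expect_error(mixture_chisq_pvalue(1, c(0, 0)), "zero")
})

test_that("Liu and Davies agree to two significant figures", {
  set.seed(56)
  for (rep in 1:10) {
    cs <- rexp(sample(2:8, 1))
    q <- sum(cs) * runif(1, 1, 6)
    pd <- suppressWarnings(mixture_chisq_pvalue(q, cs, method = "davies"))
    pl <- mixture_chisq_pvalue(q, cs, method = "liu")
    if (pd > 1e-4 && pd < 0.5) {
      expect_equal(pl, pd, tolerance = 0.05)
    }
  }
})

test_that("Q is invariant to phenotype location shifts", {
  g <- make_genotypes(25, 3, seed = 57)
  w <- beta_maf_weights(g$variants$maf)$scaled
  set.seed(58)
  y <- rnorm(25)
  pr <- null_projection(cbind(rnorm(25)))
  expect_equal(skat_q(y, pr, g, w), skat_q(y + 7, pr, g, w),
               tolerance = 1e-9)
})

test_that("SKAT-O degenerates to SKAT for a single variant", {
  g <- make_genotypes(60, 1, maf = 0.1, seed = 59)
  set.seed(60)
  y <- rnorm(60)
  pr <- null_projection(n = 60)
  so <- skat_o_test(y, pr, g, n_mc = 500, seed = 61)
  sk <- skat_test(y, pr, g, pvalue_method = "liu")
  expect_equal(so$min_p, sk$p_value, tolerance = 1e-8)
  expect_equal(so$p_value, sk$p_value, tolerance = 0.1)
})

test_that("SKAT-O favours burden-like rho under same-sign effects", {
  set.seed(62)
  hits <- 0
  for (rep in 1:10) {
    g <- make_genotypes(150, 8, maf = runif(8, 0.02, 0.2))
    y <- drop(g$counts %*% rep(0.35, 8)) + rnorm(150)
    pr <- null_projection(n = 150)
    so <- skat_o_test(y, pr, g, n_mc = 300, seed = rep)
    sk <- skat_test(y, pr, g, pvalue_method = "liu")
    if (so$min_p <= sk$p_value) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
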