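test_that("the effect-size rule gives the anchor magnitudes", {
  expect_equal(effect_size_rule(0.0001), 1.2)
  expect_equal(effect_size_rule(0.01), 0.6)
  expect_equal(effect_size_rule(c(0.001, 0.1), effect_c = 0.5), c(1.5, 0.5))
})

test_that("simulated genotypes satisfy the container invariants", {
  g <- simulate_genotypes(300, 41, seed = 70)
  expect_equal(dim(g$counts), c(300L, 41L))
  expect_true(all(g$counts %in% c(0, 1, 2)))
  expect_false(anyDuplicated(g$variants$variant_id) > 0)
  # realised MAFs polymorphic and strictly below the ceiling
  expect_true(all(g$variants$maf > 0 & g$variants$maf < 0.01))
  expect_equal(g$variants$maf, compute_maf(g$counts), tolerance = 1e-12)
  # reproducible
  g2 <- simulate_genotypes(300, 41, seed = 70)
  expect_identical(g$counts, g2$counts)
})

test_that("realised MAF tracks the analytic truncated power-law mean", {
  # wide frequency band so sampling noise is small relative to the mean
  lo <- 0.01; hi <- 0.2
  analytic <- rvlrt:::mean_trunc_powerlaw(lo, hi, 1)
  set.seed(71)
  mafs <- unlist(lapply(1:50, function(i) {
    simulate_genotypes(400, 10, maf_range = c(lo, hi),
                       haplotype_pool_size = 1000, seed = 71 + i)$variants$maf
  }))
  expect_lt(abs(mean(mafs) - analytic) / analytic, 0.1)
})

test_that("covariates are standard normal plus Bernoulli(0.5)", {
  cv <- simulate_covariates(10000, seed = 72)
  expect_lt(abs(mean(cv$x1)), 0.05)
  expect_lt(abs(sd(cv$x1) - 1), 0.05)
  expect_true(all(cv$x2 %in% c(0, 1)))
  expect_lt(abs(mean(cv$x2) - 0.5), 0.02)
  expect_identical(cv, simulate_covariates(10000, seed = 72))
})

test_that("effect assignment respects counts, signs and the MAF rule", {
  g <- simulate_genotypes(300, 41, seed = 73)
  eff <- assign_effects(g, causal_fraction = 0.3, negative_fraction = 0,
                        seed = 74)
  expect_equal(sum(eff$causal), 12L) # round(0.3 * 41)
  expect_true(all(eff$gamma[eff$causal] > 0))
  expect_equal(eff$gamma[eff$causal],
               effect_size_rule(eff$maf[eff$causal]), tolerance = 1e-12)
  expect_true(all(eff$gamma[!eff$causal] == 0))
  eff50 <- assign_effects(g, negative_fraction = 0.5, seed = 75)
  expect_equal(sum(eff50$gamma[eff50$causal] < 0), 6L) # round(0.5 * 12)
  expect_equal(abs(eff50$gamma[eff50$causal]),
               effect_size_rule(eff50$maf[eff50$causal]), tolerance = 1e-12)
})

test_that("null phenotypes with vanishing noise are exact in the covariates", {
  cv <- simulate_covariates(50, seed = 76)
  y <- simulate_phenotype(cv, noise_sd = 1e-12, null = TRUE, seed = 77)
  expect_equal(y, 0.5 * cv$x1 + 0.5 * cv$x2, tolerance = 1e-9)
})

test_that("phenotype variance decomposes as the generative model predicts", {
  set.seed(78)
  n <- 40000
  g <- make_genotypes(n, 5, maf = runif(5, 0.05, 0.2))
  cv <- simulate_covariates(n)
  eff <- assign_effects(g, causal_fraction = 1, negative_fraction = 0.4)
  y <- simulate_phenotype(cv, g, eff, noise_sd = 1)
  v_pred <- 0.25 + 0.25 * 0.25 +
    sum(eff$gamma^2 * 2 * g$variants$maf * (1 - g$variants$maf)) + 1
  expect_lt(abs(var(y) - v_pred) / v_pred, 0.05)
})

test_that("the dataset wrapper is seed-reproducible end to end", {
  s1 <- simulate_rv_dataset(100, 10, seed = 79)
  s2 <- simulate_rv_dataset(100, 10, seed = 79)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$genotypes$counts, s2$genotypes$counts)
  expect_identical(s1$effects, s2$effects)
  # random-effect regime draws per-variant effects from the weighted law
  s3 <- simulate_rv_dataset(100, 10, lambda_true = 1, seed = 80)
  expect_true(all(s3$effects$causal))
  expect_true(any(s3$effects$gamma < 0) && any(s3$effects$gamma > 0))
})
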