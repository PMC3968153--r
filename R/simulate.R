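#' Simulate rare-variant genotypes from a power-law site frequency spectrum
#'
#' A self-contained surrogate for coalescent genotype simulation: site
#' MAFs are drawn from a truncated power-law spectrum (density
#' proportional to `maf^-sfs_alpha` on `maf_range`; the default
#' `sfs_alpha = 1` is the neutral 1/x spectrum), a pool of
#' `2 * haplotype_pool_size` haplotypes with independent sites at those
#' frequencies is built, and each individual is formed as a random pair of
#' pool haplotypes (introducing mild sharing-induced correlation between
#' carriers). Sites that come out monomorphic in the sampled cohort, or
#' whose realised MAF reaches the ceiling, are redrawn so the returned
#' matrix has exactly `m_target` polymorphic rare variants.
#'
#' @param n Sample count.
#' @param m_target Number of variants to emit.
#' @param maf_range Frequency floor and ceiling for the rare pool;
#'   default `c(5e-4, 0.01)`.
#' @param sfs_alpha Power-law exponent of the MAF spectrum (>= 0).
#' @param haplotype_pool_size Number of founder individuals behind the
#'   haplotype pool (pool holds twice this many haplotypes).
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] whose stored MAF is the realised
#'   (in-sample) frequency.
#' @export
simulate_genotypes <- function(n, m_target, maf_range = c(5e-4, 0.01),
                               sfs_alpha = 1, haplotype_pool_size = 500,
                               seed = NULL) {
  stopifnot(n >= 2, m_target >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] < maf_range[2])
  n_hap <- 2L * haplotype_pool_size
  if (maf_range[2] * n_hap < 1) {
    stop("infeasible config: frequency ceiling times pool size is below one carrier")
  }
  if (!is.null(seed)) set.seed(seed)
  draw_block <- function(k) {
    maf <- rtrunc_powerlaw(k, maf_range[1], maf_range[2], sfs_alpha)
    # haplotype pool with independent sites at the drawn frequencies
    H <- matrix(stats::rbinom(n_hap * k, 1, rep(maf, each = n_hap)), n_hap, k)
    i1 <- sample.int(n_hap, n, replace = TRUE)
    i2 <- sample.int(n_hap, n, replace = TRUE)
    H[i1, , drop = FALSE] + H[i2, , drop = FALSE]
  }
  counts <- matrix(0, n, 0)
  tries <- 0L
  while (ncol(counts) < m_target) {
    tries <- tries + 1L
    if (tries > 200L) stop("could not realise enough polymorphic rare variants")
    blk <- draw_block(max(m_target - ncol(counts), 8L))
    raf <- colMeans(blk) / 2
    keep <- raf > 0 & raf < maf_range[2] & raf <= 0.5
    counts <- cbind(counts, blk[, keep, drop = FALSE])
  }
  counts <- counts[, seq_len(m_target), drop = FALSE]
  dimnames(counts) <- list(paste0("sample", seq_len(n)),
                           paste0("v", seq_len(m_target)))
  genotype_matrix(counts)
}

# inverse-CDF sampler for density proportional to x^-alpha on [lo, hi]
rtrunc_powerlaw <- function(k, lo, hi, alpha) {
  u <- stats::runif(k)
  if (abs(alpha - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a1 <- 1 - alpha
    (lo^a1 + u * (hi^a1 - lo^a1))^(1 / a1)
  }
}

# analytic mean of the truncated power-law spectrum (used by tests)
mean_trunc_powerlaw <- function(lo, hi, alpha) {
  if (abs(alpha - 1) < 1e-12) {
    (hi - lo) / log(hi / lo)
  } else {
    a1 <- 1 - alpha
    a2 <- 2 - alpha
    (a1 / a2) * (hi^a2 - lo^a2) / (hi^a1 - lo^a1)
  }
}

#' Simulate the study covariates
#'
#' Two mutually independent covariates: `x1` standard normal and `x2`
#' Bernoulli with rate 0.5.
#'
#' @param n Sample count (>= 2).
#' @param seed Optional integer seed.
#' @return A tibble with columns `x1`, `x2`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5))
}

#' Assign causal effects to rare variants
#'
#' Draws the causal subset (nearest integer to `causal_fraction * m`,
#' uniformly among the variants) and sets each causal effect magnitude by
#' the MAF-dependent rule `|gamma_j| = effect_c * |log10(MAF_j)|`, so the
#' default `effect_c = 0.3` gives 1.2 at MAF 1e-4 and 0.6 at MAF 0.01.
#' The nearest integer to `negative_fraction` of the causal effects is
#' negated, chosen uniformly.
#'
#' @param g A [genotype_matrix()] of (rare) variants.
#' @param causal_fraction Fraction of variants that are causal (default
#'   0.30).
#' @param effect_c Proportionality constant of the effect rule (default
#'   0.3).
#' @param negative_fraction Fraction of causal effects that are negative
#'   (0, 0.3 or 0.5 in the study designs; any value in `[0, 1]` accepted).
#' @param seed Optional integer seed.
#' @return A tibble with one row per variant: `variant_id`, `maf`,
#'   `causal` (logical), `gamma` (0 for non-causal variants).
#' @export
assign_effects <- function(g, causal_fraction = 0.3, effect_c = 0.3,
                           negative_fraction = 0, seed = NULL) {
  stopifnot(inherits(g, "genotype_matrix"),
            causal_fraction >= 0, causal_fraction <= 1,
            negative_fraction >= 0, negative_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(g$counts)
  q <- round(causal_fraction * m)
  causal <- rep(FALSE, m)
  gamma <- rep(0, m)
  if (q > 0) {
    idx <- sample.int(m, q)
    causal[idx] <- TRUE
    gamma[idx] <- effect_size_rule(g$variants$maf[idx], effect_c)
    n_neg <- round(negative_fraction * q)
    if (n_neg > 0) {
      neg <- sample(idx, n_neg)
      gamma[neg] <- -gamma[neg]
    }
  }
  tibble::tibble(variant_id = g$variants$variant_id, maf = g$variants$maf,
                 causal = causal, gamma = gamma)
}

#' MAF-dependent effect-size rule
#'
#' `|gamma| = effect_c * |log10(maf)|`: rarer variants get larger
#' per-allele effects.
#'
#' @param maf Minor allele frequency vector in `(0, 1)`.
#' @param effect_c Proportionality constant (default 0.3).
#' @return Vector of absolute effect sizes.
#' @export
effect_size_rule <- function(maf, effect_c = 0.3) {
  stopifnot(all(maf > 0), all(maf < 1))
  effect_c * abs(log10(maf))
}

#' Simulate a continuous phenotype
#'
#' `y = 0.5 x1 + 0.5 x2 + sum_c gamma_c g_c + e`, `e ~ N(0, noise_sd^2)`.
#' With `null = TRUE` the genetic sum is dropped, giving the
#' type-I-error generating model.
#'
#' @param covariates Tibble/data frame with the covariate columns.
#' @param g A [genotype_matrix()] (ignored under `null = TRUE`).
#' @param effects Effect tibble from [assign_effects()] (ignored under
#'   `null = TRUE`).
#' @param covariate_betas Coefficients for the covariates (recycled),
#'   default `c(0.5, 0.5)`.
#' @param noise_sd Residual standard deviation (default 1).
#' @param null Drop the genetic contribution.
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector of length `n`.
#' @export
simulate_phenotype <- function(covariates, g = NULL, effects = NULL,
                               covariate_betas = c(0.5, 0.5), noise_sd = 1,
                               null = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Xc <- as.matrix(tibble::as_tibble(covariates))
  betas <- rep_len(covariate_betas, ncol(Xc))
  mu <- drop(Xc %*% betas)
  if (!null) {
    stopifnot(inherits(g, "genotype_matrix"), !is.null(effects))
    stopifnot(nrow(effects) == ncol(g$counts))
    mu <- mu + drop(g$counts %*% effects$gamma)
  }
  mu + stats::rnorm(length(mu), sd = noise_sd)
}

#' Simulate a complete rare-variant dataset
#'
#' One call wiring together [simulate_genotypes()],
#' [simulate_covariates()], [assign_effects()] and
#' [simulate_phenotype()], with child seeds derived from one root seed.
#' With `lambda_true > 0` the genetic effects are instead drawn from the
#' weighted mixed-model generative law
#' `gamma_j ~ N(0, lambda_true * noise_sd^2 * w_j^2)` (Beta(1, 25)
#' max-scaled weights), which is the regime used for variance-ratio
#' recovery checks.
#'
#' @param n Sample count.
#' @param m_target Number of rare variants.
#' @param null Generate under the no-association model.
#' @param causal_fraction,effect_c,negative_fraction Passed to
#'   [assign_effects()] (fixed-effect regime).
#' @param lambda_true If positive, use the random-effect regime with this
#'   variance ratio instead of the fixed-effect rule.
#' @param maf_range,sfs_alpha,haplotype_pool_size Passed to
#'   [simulate_genotypes()].
#' @param covariate_betas,noise_sd Passed to [simulate_phenotype()].
#' @param seed Root integer seed.
#' @return List with `genotypes`, `data` (tibble: `sample_id`, `y`, `x1`,
#'   `x2`), `effects`, and the seeds used.
#' @export
simulate_rv_dataset <- function(n, m_target, null = FALSE,
                                causal_fraction = 0.3, effect_c = 0.3,
                                negative_fraction = 0, lambda_true = 0,
                                maf_range = c(5e-4, 0.01), sfs_alpha = 1,
                                haplotype_pool_size = 500,
                                covariate_betas = c(0.5, 0.5), noise_sd = 1,
                                seed = NULL) {
  seed <- seed %||% sample.int(2^31 - 2, 1)
  g <- simulate_genotypes(n, m_target, maf_range, sfs_alpha,
                          haplotype_pool_size, seed = child_seed(seed, 1L))
  covs <- simulate_covariates(n, seed = child_seed(seed, 2L))
  if (lambda_true > 0) {
    set.seed(child_seed(seed, 3L))
    w <- beta_maf_weights(g$variants$maf)$scaled
    gamma <- stats::rnorm(ncol(g$counts),
                          sd = sqrt(lambda_true) * noise_sd * w)
    effects <- tibble::tibble(variant_id = g$variants$variant_id,
                              maf = g$variants$maf,
                              causal = TRUE, gamma = gamma)
  } else {
    effects <- assign_effects(g, causal_fraction, effect_c,
                              negative_fraction, seed = child_seed(seed, 3L))
  }
  y <- simulate_phenotype(covs, g, effects, covariate_betas, noise_sd,
                          null = null, seed = child_seed(seed, 4L))
  data <- tibble::tibble(sample_id = g$samples, y = y,
                         x1 = covs$x1, x2 = covs$x2)
  list(genotypes = g, data = data, effects = effects, seed = seed)
}
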