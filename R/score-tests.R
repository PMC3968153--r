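#' Unified score statistic for burden / SKAT
#'
#' Computes `Q = r' G W^{1/2} R_rho W^{1/2} G' r` where `r = P0 y` are the
#' null-model residuals, `W = diag(w^2)` the squared scaled MAF weights
#' and `R_rho = (1 - rho) I + rho J` the exchangeable correlation among
#' variant effects. `rho = 0` gives the SKAT statistic
#' `sum_j w_j^2 (g_j'r)^2`; `rho = 1` collapses to the squared weighted
#' burden score `(sum_j w_j g_j'r)^2`.
#'
#' @param y Phenotype vector.
#' @param proj A [null_projection()].
#' @param g A [genotype_matrix()] aligned to `y`.
#' @param weights Scaled per-variant weights (default Beta(1, 25) from the
#'   stored MAF).
#' @param rho Effect-correlation parameter in `[0, 1]`.
#' @return The scalar statistic `Q >= 0`.
#' @export
skat_q <- function(y, proj, g, weights = NULL, rho = 0) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(weights)) weights <- beta_maf_weights(g$variants$maf)$scaled
  r <- project_null(proj, y)
  s <- weights * drop(crossprod(g$counts, r))   # W^{1/2} G' r
  (1 - rho) * sum(s^2) + rho * sum(s)^2
}

#' Mixture-of-chi-square weights for the score statistic's null
#'
#' Under `H0`, `Q` is distributed as `sum_j c_j chi^2_1` with `c_j` the
#' eigenvalues of `sigma0^2 A' P0 A`, `A = G W^{1/2} R_rho^{1/2}`. The
#' exchangeable square root is applied in closed form
#' (`R_rho^{1/2} = a I + b J`, a rank-one update), and `sigma0^2` uses the
#' REML-style divisor `n - p - 1`.
#'
#' @inheritParams skat_q
#' @param sigma0_sq Null residual variance; default `r'r / (n - p - 1)`.
#' @return Numeric vector of non-negative mixture weights (descending).
#' @export
null_mixture_weights <- function(y, proj, g, weights = NULL, rho = 0,
                                 sigma0_sq = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(weights)) weights <- beta_maf_weights(g$variants$maf)$scaled
  m <- ncol(g$counts)
  if (is.null(sigma0_sq)) {
    r <- project_null(proj, y)
    sigma0_sq <- sum(r^2) / (length(y) - proj$rank)
  }
  # closed-form exchangeable square root
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  Aw <- sweep(g$counts, 2, weights, `*`)        # G W^{1/2}
  A <- a * Aw + b * outer(rowSums(Aw), rep(1, m))
  PA <- project_null(proj, A)
  ev <- eigen(crossprod(PA), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12 * max(ev, 0)]
  sigma0_sq * ev
}

#' P-value for a weighted sum of 1-df chi-squares
#'
#' `method = "davies"` inverts the characteristic function numerically
#' (Imhof's integral, absolute error target 1e-6); `method = "liu"` uses
#' the four-moment match to a shifted chi-square. Davies falls back to
#' Liu with a warning if the quadrature fails to converge. P-values are
#' clipped to `(1e-12, 1]`.
#'
#' @param q_obs Observed statistic.
#' @param weights Non-negative mixture weights, not all zero.
#' @param method `"davies"` (default) or `"liu"`.
#' @return Upper-tail probability `P(sum_j c_j chi^2_1 > q_obs)`.
#' @export
mixture_chisq_pvalue <- function(q_obs, weights, method = c("davies", "liu")) {
  method <- match.arg(method)
  weights <- weights[weights > 0]
  if (length(weights) == 0L) stop("all mixture weights are zero")
  if (q_obs <= 0) return(1)
  # degenerate mixtures have exact chi-square tails (and the oscillatory
  # quadrature converges poorly for a single weight)
  if (length(unique(weights)) == 1L) {
    return(min(max(stats::pchisq(q_obs / weights[1], df = length(weights),
                                 lower.tail = FALSE), 1e-12), 1))
  }
  p <- if (method == "davies") {
    p_try <- tryCatch(imhof_pvalue(q_obs, weights), error = function(e) NA_real_)
    if (is.na(p_try)) {
      warning("characteristic-function inversion failed; falling back to Liu")
      liu_pvalue(q_obs, weights)
    } else p_try
  } else {
    liu_pvalue(q_obs, weights)
  }
  min(max(p, 1e-12), 1)
}

# Imhof's inversion formula for P(Q > q), Q = sum c_j chi^2_1.
# The integrand is oscillatory, so the quadrature is attempted over a
# ladder of tolerances; the caller falls back to Liu if all fail.
imhof_pvalue <- function(q, cs) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(cs, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(cs^2, u^2))))
    ifelse(u == 0, 0, sin(theta) / (u * rho))
  }
  for (tol in c(1e-10, 1e-8, 1e-6)) {
    int <- tryCatch(
      stats::integrate(integrand, 0, Inf, abs.tol = tol, rel.tol = tol,
                       subdivisions = 5000L, stop.on.error = TRUE),
      error = function(e) NULL
    )
    if (!is.null(int)) return(0.5 + int$value / pi)
  }
  stop("Imhof quadrature did not converge")
}

# Liu-Tang-Zhang four-moment match to a (noncentral) chi-square.
liu_pvalue <- function(q, cs) {
  c1 <- sum(cs); c2 <- sum(cs^2); c3 <- sum(cs^3); c4 <- sum(cs^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  stats::pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}

# vectorised Liu p-values for many statistics under one weight set
liu_pvalue_vec <- function(qs, cs) {
  vapply(qs, liu_pvalue, numeric(1), cs = cs)
}

#' Burden and SKAT score tests
#'
#' Convenience wrappers around [skat_q()], [null_mixture_weights()] and
#' [mixture_chisq_pvalue()] for the two fixed-correlation score tests:
#' the burden test (`rho = 1`, powerful when effects share a direction)
#' and SKAT (`rho = 0`, robust to mixed effect signs).
#'
#' @inheritParams skat_q
#' @param pvalue_method `"davies"` or `"liu"`.
#' @return A tibble with columns `method`, `Q`, `p_value`, `rho`,
#'   `pvalue_method`.
#' @export
skat_test <- function(y, proj, g, weights = NULL,
                      pvalue_method = c("davies", "liu")) {
  score_test_fixed_rho(y, proj, g, weights, rho = 0, label = "SKAT",
                       pvalue_method = match.arg(pvalue_method))
}

#' @rdname skat_test
#' @export
burden_test <- function(y, proj, g, weights = NULL,
                        pvalue_method = c("davies", "liu")) {
  score_test_fixed_rho(y, proj, g, weights, rho = 1, label = "burden",
                       pvalue_method = match.arg(pvalue_method))
}

score_test_fixed_rho <- function(y, proj, g, weights, rho, label,
                                 pvalue_method) {
  if (is.null(weights)) weights <- beta_maf_weights(g$variants$maf)$scaled
  q <- skat_q(y, proj, g, weights, rho = rho)
  cs <- null_mixture_weights(y, proj, g, weights, rho = rho)
  tibble::tibble(
    method = label, Q = q,
    p_value = mixture_chisq_pvalue(q, cs, method = pvalue_method),
    rho = rho, pvalue_method = pvalue_method
  )
}

#' Optimal-rho SKAT (SKAT-O) with a Monte-Carlo minimum-p null
#'
#' Computes the fixed-`rho` p-value over a grid of effect-correlation
#' values, takes the minimum as the adaptive statistic, and calibrates it
#' by Monte Carlo: null residual vectors are drawn from the fitted null
#' model, the minimum-p statistic is recomputed for each draw over the
#' same grid, and the reported p-value is the add-one tail proportion.
#' Liu p-values are used on both the observed and the simulated side so
#' the comparison is like-with-like.
#'
#' @inheritParams skat_q
#' @param rho_grid Grid of `rho` values; must contain 0 and 1. The
#'   default is the squared-decile convention
#'   `{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}`.
#' @param n_mc Number of Monte-Carlo null draws (>= 100).
#' @param seed Optional integer seed.
#' @return A tibble with columns `method`, `Q` (at the selected `rho`),
#'   `p_value`, `rho` (selected), `pvalue_method` (`"montecarlo"`),
#'   `min_p` (the observed minimum fixed-`rho` p-value).
#' @export
skat_o_test <- function(y, proj, g, weights = NULL,
                        rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                        n_mc = 2000, seed = NULL) {
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1),
            0 %in% rho_grid, 1 %in% rho_grid, n_mc >= 100)
  if (is.null(weights)) weights <- beta_maf_weights(g$variants$maf)$scaled
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  r <- project_null(proj, y)
  sigma0_sq <- sum(r^2) / (n - proj$rank)
  s <- weights * drop(crossprod(g$counts, r))
  ss2 <- sum(s^2); ss1 <- sum(s)^2
  q_obs <- (1 - rho_grid) * ss2 + rho_grid * ss1
  cs_list <- lapply(rho_grid, function(rh) {
    null_mixture_weights(y, proj, g, weights, rho = rh,
                         sigma0_sq = sigma0_sq)
  })
  p_obs <- vapply(seq_along(rho_grid),
                  function(i) liu_pvalue(q_obs[i], cs_list[[i]]), numeric(1))
  t_obs <- min(p_obs)
  i_sel <- which.min(p_obs)

  # Monte-Carlo null of the minimum-p statistic: residuals of fresh
  # Gaussian phenotypes drawn under the fitted null model
  E <- matrix(stats::rnorm(n * n_mc, sd = sqrt(sigma0_sq)), n, n_mc)
  S <- weights * crossprod(g$counts, project_null(proj, E))  # m x n_mc
  s2 <- colSums(S^2); s1 <- colSums(S)^2
  min_p_null <- rep(Inf, n_mc)
  for (i in seq_along(rho_grid)) {
    qn <- (1 - rho_grid[i]) * s2 + rho_grid[i] * s1
    min_p_null <- pmin(min_p_null, liu_pvalue_vec(qn, cs_list[[i]]))
  }
  p_final <- (sum(min_p_null <= t_obs) + 1) / (n_mc + 1)
  tibble::tibble(
    method = "SKAT-O", Q = q_obs[i_sel], p_value = p_final,
    rho = rho_grid[i_sel], pvalue_method = "montecarlo", min_p = t_obs
  )
}
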