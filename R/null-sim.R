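#' Simulate the exact finite-sample null of the (Re)LRT
#'
#' Uses the spectral representation of the boundary likelihood-ratio
#' statistics: with `u_1, ..., u_{n-p}` independent standard normals and
#' the eigenvalues `xi` / `mu` of the [spectral_basis],
#'
#' ```
#' N(lambda) = sum_j [lambda mu_j / (1 + lambda mu_j)] u_j^2
#' D(lambda) = sum_j u_j^2 / (1 + lambda mu_j) + sum_{j > K} u_j^2
#' LRT(lambda)   = n log(1 + N/D)       - sum_j log(1 + lambda xi_j)
#' ReLRT(lambda) = (n - p) log(1 + N/D) - sum_j log(1 + lambda mu_j)
#' ```
#'
#' and each replicate is `max(0, sup_lambda ...)`. The supremum uses the
#' same grid and golden-section refinement as the observed statistic
#' (vectorised across replicates). The tail sum of squares beyond the
#' active spectrum is drawn as a single chi-square with
#' `n - p - K` degrees of freedom, which is distributionally identical to
#' summing the individual normals.
#'
#' @param basis A [spectral_basis].
#' @param kind `"LRT"`, `"ReLRT"`, or `"both"`.
#' @param n_sims Number of null replicates (>= 100).
#' @param grid Variance-ratio search grid, see [lambda_grid()].
#' @param tol Golden-section tolerance on `log(lambda)`.
#' @param seed Optional integer seed for reproducibility.
#' @return For a single `kind`, a sorted numeric vector of `n_sims` null
#'   statistics; for `"both"`, a named list of two such vectors sharing
#'   the same underlying normal draws.
#' @export
simulate_null <- function(basis, kind = c("LRT", "ReLRT", "both"),
                          n_sims = 10000, grid = lambda_grid(), tol = 1e-4,
                          seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(basis, "spectral_basis"), n_sims >= 100)
  if (!is.null(seed)) set.seed(seed)
  mu <- basis$mu
  xi <- basis$xi
  K <- length(mu)
  if (K == 0L || length(xi) == 0L || max(c(xi, 0)) == 0) {
    # degenerate spectrum: the statistic is identically 0 under the null
    z <- rep(0, n_sims)
    return(if (kind == "both") list(LRT = z, ReLRT = z) else z)
  }
  n <- basis$n
  p <- basis$p_rank
  df_tail <- n - p - K
  if (df_tail < 0L) stop("active spectrum larger than residual dimension")
  B <- matrix(stats::rnorm(n_sims * K)^2, n_sims, K)
  tail_ss <- if (df_tail > 0L) stats::rchisq(n_sims, df_tail) else numeric(n_sims)

  want_lrt <- kind %in% c("LRT", "both")
  want_relrt <- kind %in% c("ReLRT", "both")

  # objective evaluated at one shared lambda for all replicates
  eval_grid <- function(l) {
    am <- l * mu / (1 + l * mu)
    N <- drop(B %*% am)
    D <- drop(B %*% (1 / (1 + l * mu))) + tail_ss
    core <- log1p(N / D)
    out <- list()
    if (want_lrt) out$LRT <- n * core - sum(log1p(l * xi))
    if (want_relrt) out$ReLRT <- (n - p) * core - sum(log1p(l * mu))
    out
  }
  # objective at per-replicate lambda vectors (refinement stage)
  eval_vec <- function(l, which_kind, idx) {
    Lm <- outer(l, mu)                       # |idx| x K
    Bi <- B[idx, , drop = FALSE]
    N <- rowSums(Bi * (Lm / (1 + Lm)))
    D <- rowSums(Bi / (1 + Lm)) + tail_ss[idx]
    core <- log1p(N / D)
    if (which_kind == "LRT") {
      n * core - rowSums(log1p(outer(l, xi)))
    } else {
      (n - p) * core - rowSums(log1p(Lm))
    }
  }

  pos <- grid[grid > 0]
  best <- list()
  if (want_lrt) best$LRT <- list(val = rep(0, n_sims), arg = rep(0L, n_sims))
  if (want_relrt) best$ReLRT <- list(val = rep(0, n_sims), arg = rep(0L, n_sims))
  for (gi in seq_along(pos)) {
    ev <- eval_grid(pos[gi])
    for (kd in names(best)) {
      upd <- ev[[kd]] > best[[kd]]$val
      best[[kd]]$val[upd] <- ev[[kd]][upd]
      best[[kd]]$arg[upd] <- gi
    }
  }

  refine <- function(kd) {
    b <- best[[kd]]
    idx <- which(b$arg > 0L)                  # replicates with interior max
    if (length(idx)) {
      gi <- b$arg[idx]
      lo <- ifelse(gi == 1L, pos[1] / 100, pos[pmax(gi - 1L, 1L)])
      hi <- pos[pmin(gi + 1L, length(pos))]
      val <- golden_max_vec(function(l, sub) eval_vec(l, kd, idx[sub]),
                            log(lo), log(hi), tol)
      b$val[idx] <- pmax(b$val[idx], val)
    }
    sort(pmax(b$val, 0))
  }
  res <- lapply(names(best), refine)
  names(res) <- names(best)
  if (kind == "both") res else res[[kind]]
}

# Vectorised golden-section maximisation: each case has its own bracket
# [loglo_i, loghi_i]; f(lambda_vec, sub) evaluates case subset `sub` at
# its own lambda. Returns the best value found per case.
golden_max_vec <- function(f, loglo, loghi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- loglo; b <- loghi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  all_idx <- seq_along(a)
  f1 <- f(exp(x1), all_idx); f2 <- f(exp(x2), all_idx)
  while (max(b - a) > tol) {
    right <- f1 < f2
    # shrink left side where right is better
    a[right] <- x1[right]; x1[right] <- x2[right]; f1[right] <- f2[right]
    x2[right] <- a[right] + gr * (b[right] - a[right])
    # shrink right side elsewhere
    left <- !right
    b[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- b[left] - gr * (b[left] - a[left])
    if (any(right)) f2[right] <- f(exp(x2[right]), which(right))
    if (any(left)) f1[left] <- f(exp(x1[left]), which(left))
  }
  pmax(f1, f2)
}

#' Empirical p-value from a simulated null sample
#'
#' `p = (#\{null >= statistic\} + 1) / (n_sims + 1)`, the standard
#' add-one Monte-Carlo estimator, so `p` is never 0 and has floor
#' `1 / (n_sims + 1)`.
#'
#' @param statistic Observed test statistic.
#' @param null_sample Numeric vector of simulated null statistics.
#' @return p-value in `(0, 1]`.
#' @export
pvalue_from_null <- function(statistic, null_sample) {
  if (length(null_sample) == 0L) stop("empty null sample")
  (sum(null_sample >= statistic) + 1) / (length(null_sample) + 1)
}

#' Conservative 50:50 chi-square mixture p-value
#'
#' The classical boundary approximation for a single variance component:
#' an equal mixture of a point mass at zero and a 1-df chi-square. Known
#' to be conservative in finite samples relative to the exact simulated
#' null; provided as a cross-check utility only, never used as the
#' default p-value.
#'
#' @param statistic Observed (Re)LRT statistic.
#' @return p-value in `(0, 1]`.
#' @export
chibarsq_pvalue <- function(statistic) {
  if (statistic <= 0) return(1)
  0.5 * stats::pchisq(statistic, df = 1, lower.tail = FALSE)
}
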