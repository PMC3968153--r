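#' Profile log-likelihoods for the variance-ratio parameter
#'
#' Under the model `y = Xd b + e`, `Var(e) = sigma^2 (I + lambda C)` with
#' `C` the weighted genetic covariance (`G W G'` or a kernel `K`) and
#' `lambda = tau / sigma^2`, profiling out the fixed effects (GLS) and
#' `sigma^2` leaves one-dimensional objectives in `lambda`:
#'
#' * ML:   `l(lambda)  = -(n/2)   log(RSS_lambda) - (1/2) log|V_lambda|`
#' * REML: `lr(lambda) = -((n-p-1)/2) log(RSS_lambda) - (1/2) log|V_lambda|
#'                        - (1/2) log|Xd' V_lambda^{-1} Xd|`
#'
#' (constants independent of `lambda` dropped), where
#' `RSS_lambda = r' V_lambda^{-1} r` at the GLS residual `r` and
#' `V_lambda = I + lambda C`. Both are evaluated through the eigenfactor
#' stored in the [spectral_basis], costing `O(n (p+1))` per `lambda`.
#'
#' @param lambda Non-negative variance ratio (vectorised).
#' @param y Phenotype vector.
#' @param proj A [null_projection()].
#' @param basis A [spectral_basis] for the same data.
#' @return Numeric vector of objective values, one per `lambda`.
#' @export
profile_ml_loglik <- function(lambda, y, proj, basis) {
  pl <- profile_parts(lambda, y, proj, basis)
  unname(-(basis$n / 2) * log(pl$rss) - pl$logdet_v / 2)
}

#' @rdname profile_ml_loglik
#' @export
profile_reml_loglik <- function(lambda, y, proj, basis) {
  pl <- profile_parts(lambda, y, proj, basis)
  if (basis$n - basis$p_rank == 1L) {
    warning("only one residual degree of freedom; REML objective is fragile")
  }
  unname(-((basis$n - basis$p_rank) / 2) * log(pl$rss) - pl$logdet_v / 2 -
           pl$logdet_xvx / 2)
}

# Shared GLS computation. V^{-1} = I - U diag(a) U' with
# a_j = lambda ev_j / (1 + lambda ev_j); all inner products reduce to
# precomputable cross-products with U.
profile_parts <- function(lambda, y, proj, basis) {
  stopifnot(all(lambda >= 0), all(is.finite(lambda)))
  Xd <- proj$X_design
  U <- basis$U
  ev <- basis$ev
  Uy <- drop(crossprod(U, y))
  UX <- crossprod(U, Xd)
  XtX <- crossprod(Xd)
  Xty <- drop(crossprod(Xd, y))
  yty <- sum(y^2)
  out <- vapply(lambda, function(l) {
    a <- l * ev / (1 + l * ev)
    M <- XtX - crossprod(UX, a * UX)             # Xd' V^{-1} Xd
    v <- Xty - drop(crossprod(UX, a * Uy))       # Xd' V^{-1} y
    ch <- chol(M)
    b <- backsolve(ch, forwardsolve(t(ch), v))
    yVy <- yty - sum(a * Uy^2)
    rss <- max(yVy - sum(v * b), .Machine$double.xmin)
    c(rss = rss,
      logdet_v = sum(log1p(l * ev)),
      logdet_xvx = 2 * sum(log(diag(ch))))
  }, numeric(3))
  list(rss = out["rss", ], logdet_v = out["logdet_v", ],
       logdet_xvx = out["logdet_xvx", ])
}

#' Default search grid for the variance ratio
#'
#' `{0}` followed by a logarithmic grid from `1e-4` to `1e4` (81 points).
#' The same grid, with the same golden-section refinement tolerance, is
#' used for the observed statistic and for every simulated null
#' replicate, so both share any residual maximisation bias and the
#' simulated null is exact for the statistic as implemented.
#'
#' @param lo,hi Grid end points (positive).
#' @param length Number of positive grid points.
#' @return Ascending numeric vector starting at 0.
#' @export
lambda_grid <- function(lo = 1e-4, hi = 1e4, length = 81) {
  c(0, exp(seq(log(lo), log(hi), length.out = length)))
}

# Golden-section maximisation of f over log-lambda in [loglo, loghi].
golden_max <- function(f, loglo, loghi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- loglo; b <- loghi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  while ((b - a) > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    }
  }
  if (f1 >= f2) list(lambda = exp(x1), value = f1) else list(lambda = exp(x2), value = f2)
}

#' Maximise a profile objective over the variance ratio
#'
#' Coarse grid scan followed by golden-section refinement (in log-lambda)
#' inside the bracketing interval. The statistic is
#' `max(0, 2 * (sup_lambda f - f(0)))`; when the grid maximum sits at
#' `lambda = 0` the estimate is exactly 0 and the statistic 0.
#'
#' @param objective Function of `lambda` returning the (profile) objective
#'   value; must accept scalar `lambda >= 0`.
#' @param grid Search grid from [lambda_grid()].
#' @param tol Golden-section tolerance on `log(lambda)`.
#' @return List with `lambda_hat`, `statistic` and `objective_at_max`.
#' @export
maximize_over_lambda <- function(objective, grid = lambda_grid(), tol = 1e-4) {
  stopifnot(grid[1] == 0, !is.unsorted(grid))
  vals <- vapply(grid, objective, numeric(1))
  i <- which.max(vals)
  v0 <- vals[1]
  if (i == 1L) {
    return(list(lambda_hat = 0, statistic = 0, objective_at_max = v0))
  }
  if (i == length(grid)) {
    warning("variance-ratio estimate at the upper grid boundary")
  }
  lo <- if (i == 2L) grid[2] / 100 else grid[i - 1L]
  hi <- if (i == length(grid)) grid[i] else grid[i + 1L]
  ref <- golden_max(objective, log(lo), log(hi), tol)
  if (ref$value < vals[i]) ref <- list(lambda = grid[i], value = vals[i])
  stat <- 2 * (ref$value - v0)
  if (stat <= 0) {
    list(lambda_hat = 0, statistic = 0, objective_at_max = v0)
  } else {
    list(lambda_hat = ref$lambda, statistic = stat, objective_at_max = ref$value)
  }
}
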