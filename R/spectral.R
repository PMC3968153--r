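#' Spectral basis of a variance-component test
#'
#' The finite-sample null distributions of the LRT and ReLRT are driven by
#' two eigenvalue sets: `xi`, the eigenvalues of the unprojected covariance
#' factor (`W^1/2 G'G W^1/2` in the mixed-model formulation, `K` in the
#' kernel formulation), and `mu`, the eigenvalues of the same factor
#' projected off the fixed-effects space (`W^1/2 G'P0G W^1/2`, resp.
#' `K^1/2 P0 K^1/2`). A `spectral_basis` stores both (truncated and sorted
#' descending), the dimensions `n` and `p_rank = p + 1`, and the
#' eigenfactor of the marginal covariance `C = G W G'` (or `K`) used to
#' evaluate profile likelihoods in `O(n)` per candidate variance ratio.
#'
#' @name spectral_basis
#' @return A `spectral_basis` object: list with `xi`, `mu`, `n`, `p_rank`,
#'   `k_active` (number of retained `mu` eigenvalues), and the internal
#'   factor (`U`, `ev`) with `C = U diag(ev) U'`.
NULL

new_spectral_basis <- function(xi, mu, n, p_rank, U, ev) {
  structure(
    list(xi = xi, mu = mu, n = n, p_rank = p_rank,
         k_active = length(mu), U = U, ev = ev),
    class = "spectral_basis"
  )
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf(
    "<spectral_basis> n=%d, p_rank=%d, %d xi / %d mu active; max xi=%.4g\n",
    x$n, x$p_rank, length(x$xi), length(x$mu),
    if (length(x$xi)) max(x$xi) else 0
  ))
  invisible(x)
}

#' Spectral basis, mixed-model formulation
#'
#' Computes `xi` = eigenvalues of `W^1/2 G'G W^1/2` and `mu` = eigenvalues
#' of `W^1/2 G'P0G W^1/2`, with `W = diag(w^2)`, via the thin SVD of the
#' weighted genotype matrix `A = G diag(w)` (so no n x n eigenproblem is
#' formed). Eigenvalues below `1e-10 * max(xi)` are truncated: rank
#' deficiency (collinear variants, m > n) otherwise injects numerical
#' noise into the simulated null.
#'
#' @param g A [genotype_matrix()] aligned to the phenotype samples.
#' @param weights Scaled per-variant weights (the `scaled` column of
#'   [beta_maf_weights()]); defaults to Beta(1, 25) weights from the
#'   stored MAF.
#' @param proj A [null_projection()] for the same samples.
#' @return A [spectral_basis] object.
#' @export
spectral_basis_mixed <- function(g, weights = NULL, proj) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(proj, "null_projection"))
  n <- nrow(g$counts)
  if (nrow(proj$X_design) != n) stop("projection and genotypes disagree on n")
  if (n - proj$rank <= 1L) stop("residual degrees of freedom must exceed 1")
  if (is.null(weights)) weights <- beta_maf_weights(g$variants$maf)$scaled
  if (length(weights) != ncol(g$counts)) stop("weight length != variant count")
  A <- sweep(g$counts, 2, weights, `*`)
  sv <- svd(A)
  xi_all <- sv$d^2
  xi <- active_eigenvalues(xi_all)
  if (length(xi) == 0L) stop("degenerate genotype matrix: zero spectrum")
  PA <- project_null(proj, A)
  mu_all <- eigen(crossprod(PA), symmetric = TRUE, only.values = TRUE)$values
  mu <- active_eigenvalues(pmax(mu_all, 0), rel_tol = 1e-10)
  r <- length(xi)
  new_spectral_basis(xi = xi, mu = mu, n = n, p_rank = proj$rank,
                     U = sv$u[, seq_len(r), drop = FALSE], ev = xi)
}

#' Spectral basis, kernel formulation
#'
#' Computes `xi` = eigenvalues of the kernel matrix `K` and `mu` =
#' eigenvalues of `K^1/2 P0 K^1/2`. The projected spectrum is obtained on
#' the kernel's non-null eigenspace (`sqrt(e) U' P0 U sqrt(e)` with
#' `K = U diag(e) U'`), which shares its nonzero eigenvalues with
#' `K^1/2 P0 K^1/2` and avoids a second n x n eigenproblem.
#'
#' @param k An [rv_kernel()] (or symmetric PSD matrix).
#' @param proj A [null_projection()].
#' @return A [spectral_basis] object. A zero kernel raises an error of
#'   class `rvlrt_empty_set`: the set is not testable.
#' @export
spectral_basis_kernel <- function(k, proj) {
  K <- if (inherits(k, "rv_kernel")) k$values else as.matrix(k)
  stopifnot(inherits(proj, "null_projection"))
  n <- nrow(K)
  if (nrow(proj$X_design) != n) stop("projection and kernel disagree on n")
  if (n - proj$rank <= 1L) stop("residual degrees of freedom must exceed 1")
  ee <- eigen(K, symmetric = TRUE)
  if (max(ee$values) <= 0) {
    stop(structure(
      class = c("rvlrt_empty_set", "error", "condition"),
      list(message = "kernel has an empty positive spectrum; set is not testable",
           call = sys.call(-1))
    ))
  }
  if (min(ee$values) < -1e-8 * max(ee$values)) {
    stop("kernel is not positive semi-definite")
  }
  keep <- ee$values > 1e-10 * max(ee$values)
  xi <- ee$values[keep]
  U <- ee$vectors[, keep, drop = FALSE]
  PU <- project_null(proj, U)
  M <- sqrt(xi) * crossprod(U, PU) * rep(sqrt(xi), each = length(xi))
  mu_all <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mu <- active_eigenvalues(pmax(mu_all, 0))
  new_spectral_basis(xi = xi, mu = mu, n = n, p_rank = proj$rank,
                     U = U, ev = xi)
}
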