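#' Beta(1, 25) MAF weights, max-scaled
#'
#' Per-variant weights taken as the Beta(1, 25) density evaluated at the
#' minor allele frequency, `25 * (1 - maf)^24`, which up-weights rarer
#' variants. To avoid the numerical imprecision that raw Beta weights can
#' cause in variance-component software, the weights are rescaled by their
#' maximum so that `max(scaled) == 1`. Scaling is applied per tested set
#' (after the rare filter); this changes the scale of the
#' variance-component ratio, which per-set reports note.
#'
#' @param maf Numeric vector of minor allele frequencies, all in `(0, 1)`.
#' @param shape1,shape2 Beta density shape parameters; the recommended
#'   rare-variant choice `Beta(1, 25)` is the default.
#' @return A tibble with columns `maf`, `raw` (Beta density values) and
#'   `scaled` (`raw / max(raw)`), one row per variant, input order
#'   preserved.
#' @export
beta_maf_weights <- function(maf, shape1 = 1, shape2 = 25) {
  if (any(maf <= 0 | maf >= 1)) stop("MAF must lie strictly in (0, 1) for Beta weights")
  raw <- stats::dbeta(maf, shape1, shape2)
  tibble::tibble(maf = maf, raw = raw, scaled = raw / max(raw))
}

#' Weighted linear kernel
#'
#' Builds the n x n genomic-similarity kernel `K = G W G'` with
#' `W = diag(w^2)`, the covariance structure shared by the weighted
#' mixed-effects model (random effects with variance `tau * w_j^2`) and
#' its kernel-machine formulation (random effect `h` with covariance
#' `tau * K`). Additional kernels (plain linear, weighted IBS, Gaussian,
#' polynomial) share the interface but are experimental: only the
#' weighted linear kernel participates in the validated mixed/kernel
#' equivalences.
#'
#' @param g A [genotype_matrix()].
#' @param weights Scaled weight vector (one per variant), e.g. the
#'   `scaled` column of [beta_maf_weights()]. Ignored by unweighted kinds.
#' @param kind One of `"linear.weighted"` (default), `"linear"`,
#'   `"IBS.weighted"`, `"gaussian"`, `"polynomial"`.
#' @param gaussian_sd Bandwidth for the Gaussian kernel.
#' @param poly_degree Degree for the polynomial kernel.
#' @return An object of class `rv_kernel`: list with `values` (n x n
#'   symmetric PSD matrix), `kind`, and `weights`.
#' @export
rv_kernel <- function(g, weights = NULL,
                      kind = c("linear.weighted", "linear", "IBS.weighted",
                               "gaussian", "polynomial"),
                      gaussian_sd = 1, poly_degree = 2) {
  kind <- match.arg(kind)
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$counts
  m <- ncol(G)
  if (kind %in% c("linear.weighted", "IBS.weighted")) {
    if (is.null(weights)) weights <- beta_maf_weights(g$variants$maf)$scaled
    if (length(weights) != m) stop("weight vector length must match variant count")
  }
  K <- switch(kind,
    linear.weighted = {
      A <- sweep(G, 2, weights, `*`)
      tcrossprod(A)
    },
    linear = tcrossprod(G),
    IBS.weighted = {
      # IBS similarity per variant: 2 - |g_i - g_j|, weighted by w^2
      n <- nrow(G)
      K <- matrix(0, n, n)
      w2 <- weights^2
      for (j in seq_len(m)) {
        d <- abs(outer(G[, j], G[, j], `-`))
        K <- K + w2[j] * (2 - d)
      }
      K
    },
    gaussian = {
      d2 <- as.matrix(stats::dist(G))^2
      exp(-d2 / (2 * gaussian_sd^2 * m))
    },
    polynomial = (1 + tcrossprod(G))^poly_degree
  )
  K <- (K + t(K)) / 2
  structure(list(values = K, kind = kind, weights = weights),
            class = "rv_kernel")
}

#' @export
print.rv_kernel <- function(x, ...) {
  cat(sprintf("<rv_kernel> kind=%s, n=%d\n", x$kind, nrow(x$values)))
  invisible(x)
}

#' Symmetric positive semi-definite square root
#'
#' Computed by symmetric eigendecomposition; eigenvalues below
#' `1e-10 * max(eigenvalue)` are clamped to zero, so mildly indefinite
#' inputs arising from float noise are projected onto the PSD cone.
#'
#' @param k An `rv_kernel` or a symmetric numeric matrix.
#' @return Symmetric PSD matrix `S` with `S %*% S` reproducing the input.
#' @export
kernel_sqrt <- function(k) {
  K <- if (inherits(k, "rv_kernel")) k$values else as.matrix(k)
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("kernel_sqrt needs a symmetric matrix")
  }
  ee <- eigen(K, symmetric = TRUE)
  vals <- ee$values
  vals[vals < 1e-10 * max(vals, 0)] <- 0
  S <- ee$vectors %*% (sqrt(vals) * t(ee$vectors))
  (S + t(S)) / 2
}

#' Residual projector off the null-model design
#'
#' Builds `P0 = I - Xd (Xd'Xd)^{-1} Xd'` for the design `Xd = [1, X]`
#' (intercept plus covariates), the projector onto the orthogonal
#' complement of the fixed-effects column space used by every test's null
#' model.
#'
#' @param X Covariate matrix (n x p), or `NULL`/zero-column for an
#'   intercept-only null model.
#' @param n Sample count; required when `X` is `NULL`.
#' @return An object of class `null_projection`: list with `X_design`
#'   (n x (p+1)), `P0` (n x n), `rank` (p+1) and the QR factorisation of
#'   the design used for fast projections.
#' @export
null_projection <- function(X = NULL, n = NULL) {
  if (is.null(X) || (is.matrix(X) && ncol(X) == 0L)) {
    if (is.null(n)) stop("n is required for an intercept-only projection")
    Xd <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    n <- nrow(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    Xd <- cbind(`(Intercept)` = 1, X)
  }
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    stop("null-model design is rank deficient; collinear column(s): ",
         paste(colnames(Xd)[qrd$pivot[(qrd$rank + 1):ncol(Xd)]], collapse = ", "))
  }
  Q <- qr.Q(qrd)
  P0 <- diag(n) - tcrossprod(Q)
  P0 <- (P0 + t(P0)) / 2
  structure(list(X_design = Xd, P0 = P0, rank = ncol(Xd), qr = qrd),
            class = "null_projection")
}

#' Apply the residual projector to a vector or matrix
#'
#' Uses the stored QR factorisation (`O(np)` per column) rather than the
#' dense `P0` multiply.
#'
#' @param proj A [null_projection()].
#' @param v Numeric vector or matrix with `n` rows.
#' @return The projected residuals `P0 v`.
#' @export
project_null <- function(proj, v) {
  stopifnot(inherits(proj, "null_projection"))
  v <- as.matrix(v)
  r <- qr.resid(proj$qr, v)
  if (ncol(r) == 1L) drop(r) else r
}
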