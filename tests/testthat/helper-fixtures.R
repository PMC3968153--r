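# Shared fixtures and independent oracles for the test suite.

# small random dosage matrix with controllable allele frequencies
make_genotypes <- function(n, m, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.4)
  repeat {
    counts <- sapply(maf, function(p) rbinom(n, 2, p))
    if (all(colSums(counts) > 0)) break
  }
  dimnames(counts) <- list(paste0("s", seq_len(n)), paste0("v", seq_len(m)))
  genotype_matrix(counts)
}

make_data <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    y = rnorm(n),
    x1 = rnorm(n),
    x2 = rbinom(n, 1, 0.5)
  )
}

# dense-matrix ML oracle: generic numerical maximization of the full
# Gaussian log-likelihood over (beta, log sigma2) at fixed lambda
dense_ml_loglik <- function(lambda, y, X, C) {
  n <- length(y)
  Xd <- cbind(1, X)
  V <- diag(n) + lambda * C
  nll <- function(par) {
    b <- par[seq_len(ncol(Xd))]
    s2 <- exp(par[ncol(Xd) + 1])
    r <- y - drop(Xd %*% b)
    0.5 * (n * log(2 * pi * s2) + as.numeric(determinant(V)$modulus) +
             drop(crossprod(r, solve(s2 * V, r))))
  }
  fit <- optim(c(rep(0, ncol(Xd)), 0), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  -fit$value
}

# dense REML oracle via the error-contrast likelihood (direct formula)
dense_reml_loglik <- function(lambda, y, X, C) {
  n <- length(y)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  V <- diag(n) + lambda * C
  Vi <- solve(V)
  M <- t(Xd) %*% Vi %*% Xd
  b <- solve(M, t(Xd) %*% Vi %*% y)
  r <- y - drop(Xd %*% b)
  rss <- drop(crossprod(r, Vi %*% r))
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) + as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(M)$modulus) + rss / s2)
}

# dense observed (Re)LRT statistics via generic optimisation over lambda
dense_lrt_stat <- function(y, X, C, reml = FALSE) {
  f <- if (reml) dense_reml_loglik else dense_ml_loglik
  obj <- function(ll) f(exp(ll), y, X, C)
  opt <- optimize(obj, c(log(1e-6), log(1e6)), maximum = TRUE, tol = 1e-9)
  max(0, 2 * (opt$objective - f(0, y, X, C)))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_vcf <- function(extra_site = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"
  )
  if (!is.null(extra_site)) lines <- c(lines, extra_site)
  write_tmp(lines, ".vcf")
}
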