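#' Variance-component LRT / ReLRT for a rare-variant set
#'
#' Tests whether a set of (rare) variants is collectively associated with
#' a continuous phenotype by testing `H0: lambda = 0` in the weighted
#' mixed-effects model `y = b0 + X b + G gamma + e`,
#' `gamma_j ~ N(0, tau w_j^2)`, where `lambda = tau / sigma^2`. The
#' observed LRT/ReLRT statistic is obtained by maximising the profile
#' (restricted) log-likelihood over `lambda >= 0`; its exact finite-sample
#' null distribution is simulated from the spectral representation
#' ([simulate_null()]), and the p-value compares the observed statistic to
#' the simulated sample. `lambda_hat / (1 + lambda_hat)` is reported as
#' the set-level heritability.
#'
#' Methods `"LRT.M"`/`"ReLRT.M"` use the mixed-model formulation (weighted
#' genotype matrix); `"LRT.K"`/`"ReLRT.K"` use the kernel-machine
#' formulation through the n x n kernel (by default the weighted linear
#' kernel `G W G'`, under which the two formulations are equivalent).
#' Methods sharing a formulation reuse one spectral basis and one set of
#' null draws (LRT and ReLRT nulls are computed from the same normals).
#'
#' @param data Data frame (or tibble) holding the phenotype and covariate
#'   columns, one row per sample, in the genotype matrix's sample order.
#' @param genotypes A [genotype_matrix()] aligned to `data` (required for
#'   `.M` methods and to build the default kernel).
#' @param pheno_col Name of the phenotype column in `data`.
#' @param covar_cols Character vector of covariate column names (possibly
#'   empty).
#' @param methods Subset of `c("LRT.M", "ReLRT.M", "LRT.K", "ReLRT.K")`.
#' @param kernel Optional [rv_kernel()] for the `.K` methods; default is
#'   the weighted linear kernel built from `genotypes` and `weights`.
#' @param weights Scaled per-variant weights; default Beta(1, 25) weights
#'   from the stored MAF, max-scaled per set.
#' @param n_null_sims Null-simulation size per formulation (default
#'   10000, p-value floor about 1e-4).
#' @param grid Variance-ratio search grid ([lambda_grid()]); shared by the
#'   observed statistic and the simulated null.
#' @param seed Integer seed; child seeds per formulation are derived with
#'   [child_seed()] and recorded in the result.
#' @param keep_null Keep the simulated null samples in the returned object
#'   (for diagnostics/plots).
#' @return An object of class `vc_test` with a `results` tibble (one row
#'   per method: `method`, `statistic`, `lambda_hat`, `heritability`,
#'   `p_value`, `n_null_sims`, `null_zero_mass`, `seed`). Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] to extract.
#' @export
vc_test <- function(data, genotypes = NULL, pheno_col = "y",
                    covar_cols = character(),
                    methods = c("LRT.M", "ReLRT.M", "LRT.K", "ReLRT.K"),
                    kernel = NULL, weights = NULL, n_null_sims = 10000,
                    grid = lambda_grid(), seed = NULL, keep_null = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  data <- tibble::as_tibble(data)
  y <- as.numeric(data[[pheno_col]])
  if (anyNA(y)) stop("phenotype contains missing values; align first")
  X <- if (length(covar_cols)) as.matrix(data[, covar_cols, drop = FALSE]) else NULL
  n <- length(y)
  proj <- null_projection(X, n = n)

  need_m <- any(grepl("\\.M$", methods))
  need_k <- any(grepl("\\.K$", methods))
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    if (nrow(genotypes$counts) != n) stop("genotypes and data disagree on sample count")
    if (is.null(weights)) weights <- beta_maf_weights(genotypes$variants$maf)$scaled
  } else if (need_m || (need_k && is.null(kernel))) {
    stop("genotypes are required for mixed-model methods or to build the default kernel")
  }

  seed <- seed %||% sample.int(2^31 - 2, 1)
  rows <- list()
  nulls <- list()

  run_formulation <- function(basis, tags, child) {
    kinds <- sub("\\..$", "", tags)
    obj_ml <- function(l) profile_ml_loglik(l, y, proj, basis)
    obj_reml <- function(l) profile_reml_loglik(l, y, proj, basis)
    null_s <- simulate_null(basis, kind = "both", n_sims = n_null_sims,
                            grid = grid, seed = child)
    for (tag in tags) {
      kind <- sub("\\..$", "", tag)
      opt <- maximize_over_lambda(if (kind == "LRT") obj_ml else obj_reml, grid)
      ns <- null_s[[kind]]
      rows[[tag]] <<- tibble::tibble(
        method = tag,
        statistic = opt$statistic,
        lambda_hat = opt$lambda_hat,
        heritability = opt$lambda_hat / (1 + opt$lambda_hat),
        p_value = pvalue_from_null(opt$statistic, ns),
        n_null_sims = n_null_sims,
        null_zero_mass = mean(ns == 0),
        seed = child
      )
      if (keep_null) nulls[[tag]] <<- ns
    }
  }

  if (need_m) {
    basis_m <- spectral_basis_mixed(genotypes, weights, proj)
    run_formulation(basis_m, intersect(methods, c("LRT.M", "ReLRT.M")),
                    child_seed(seed, 1L))
  }
  if (need_k) {
    if (is.null(kernel)) kernel <- rv_kernel(genotypes, weights)
    basis_k <- spectral_basis_kernel(kernel, proj)
    # same child seed as the mixed formulation: under the weighted linear
    # kernel the spectra coincide, so shared draws make the two
    # formulations' p-values agree exactly
    run_formulation(basis_k, intersect(methods, c("LRT.K", "ReLRT.K")),
                    child_seed(seed, 1L))
  }

  structure(
    list(results = dplyr::bind_rows(rows[methods]),
         n = n, p_rank = proj$rank,
         m = if (!is.null(genotypes)) ncol(genotypes$counts) else NA_integer_,
         seed = seed,
         null_samples = if (keep_null) nulls else NULL),
    class = "vc_test"
  )
}

#' @export
print.vc_test <- function(x, ...) {
  cat(sprintf("Variance-component rare-variant test (n=%d, m=%s)\n",
              x$n, x$m))
  print(x$results)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.vc_test <- function(x, ...) x$results

#' @export
glance.vc_test <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, p_rank = x$p_rank,
                 n_methods = nrow(x$results), seed = x$seed)
}

#' Plot the simulated null against the observed statistic
#'
#' Histogram of the simulated finite-sample null for each method (run with
#' `keep_null = TRUE`), with the observed statistic as a vertical line.
#'
#' @param object A `vc_test` fitted with `keep_null = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_test <- function(object, ...) {
  if (is.null(object$null_samples)) {
    stop("run vc_test(..., keep_null = TRUE) to plot null distributions")
  }
  df <- purrr::imap_dfr(object$null_samples, function(v, nm) {
    tibble::tibble(method = nm, null_statistic = v)
  })
  obs <- dplyr::select(object$results, "method", "statistic")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_statistic)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$statistic),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "simulated null statistic", y = "count")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
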