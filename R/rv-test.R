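#' Set-based rare-variant association analysis
#'
#' The end-to-end pipeline behind the command-line interface: for each
#' variant set, align samples, restrict to the set's variants, apply the
#' rare-variant MAF filter, compute per-set Beta(1, 25) max-scaled
#' weights, and run the requested association tests. Sets in which no
#' polymorphic rare variant survives are reported as not testable
#' (`NA` p-values) rather than dropped.
#'
#' @param genotypes A [genotype_matrix()] (from [read_genotypes()] or
#'   [simulate_genotypes()]).
#' @param phenotypes Phenotype tibble with `sample_id`, `y` and covariate
#'   columns (from [read_phenotypes()]).
#' @param sets Named list of variant sets (from [read_variant_sets()]), or
#'   `NULL` to test all variants as one set named `"all"`.
#' @param covar_cols Covariate column names in `phenotypes` to adjust for.
#' @param methods Methods to run: any of `burden`, `SKAT`, `SKAT-O`,
#'   `LRT.M`, `ReLRT.M`, `LRT.K`, `ReLRT.K`.
#' @param maf_threshold Rare-variant MAF cutoff (default 0.01).
#' @param kernel_kind Kernel for the `.K` methods (default
#'   `"linear.weighted"`; other kinds are experimental).
#' @param n_null_sims Null-simulation size for the (Re)LRT p-values.
#' @param skato_n_mc Monte-Carlo size for the SKAT-O p-value.
#' @param seed Root seed; per-set child seeds are derived with
#'   [child_seed()] in set order and recorded in the output.
#' @return A tibble with one row per set: `set`, `m_total`, `m_rare`,
#'   `p_<method>` columns, `lambda_<method>` and `h2_<method>` columns for
#'   the (Re)LRT methods, `null_zero_mass`, `seed`, and a `note` column
#'   (`"ok"` or the reason a set was not testable).
#' @export
rv_test <- function(genotypes, phenotypes, sets = NULL,
                    covar_cols = character(),
                    methods = c("burden", "SKAT", "SKAT-O", "LRT.K", "ReLRT.K"),
                    maf_threshold = 0.01, kernel_kind = "linear.weighted",
                    n_null_sims = 10000, skato_n_mc = 2000, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotypes <- tibble::as_tibble(phenotypes)
  seed <- seed %||% sample.int(2^31 - 2, 1)
  if (is.null(sets)) {
    sets <- list(all = list(name = "all",
                            variant_ids = genotypes$variants$variant_id))
  }
  rows <- purrr::imap(sets, function(set, idx) {
    set_seed <- child_seed(seed, match(set$name, names(sets)))
    test_one_set(genotypes, phenotypes, set, covar_cols, methods,
                 maf_threshold, kernel_kind, n_null_sims, skato_n_mc,
                 set_seed)
  })
  dplyr::bind_rows(rows)
}

test_one_set <- function(genotypes, phenotypes, set, covar_cols, methods,
                         maf_threshold, kernel_kind, n_null_sims,
                         skato_n_mc, seed) {
  set_name <- set$name
  set_ids <- unique(set$variant_ids)
  base <- tibble::tibble(set = set_name, m_total = length(set_ids),
                         m_rare = 0L, seed = seed, note = "ok")
  res <- tryCatch({
    al <- align_data(genotypes, phenotypes, set)
    g_set <- al$genotypes
    base$m_total <- ncol(g_set$counts)
    g_rare <- withCallingHandlers(
      rare_filter(g_set, maf_threshold),
      warning = function(w) invokeRestart("muffleWarning")
    )
    base$m_rare <- ncol(g_rare$counts)
    data <- al$phenotypes
    w <- beta_maf_weights(g_rare$variants$maf)$scaled
    proj <- null_projection(
      if (length(covar_cols)) as.matrix(data[, covar_cols, drop = FALSE]) else NULL,
      n = nrow(data)
    )
    out <- base
    vc_methods <- intersect(methods, c("LRT.M", "ReLRT.M", "LRT.K", "ReLRT.K"))
    if (length(vc_methods)) {
      kern <- if (any(grepl("\\.K$", vc_methods)) && kernel_kind != "linear.weighted") {
        rv_kernel(g_rare, w, kind = kernel_kind)
      } else NULL
      fit <- vc_test(data, genotypes = g_rare, pheno_col = "y",
                     covar_cols = covar_cols, methods = vc_methods,
                     kernel = kern, weights = w, n_null_sims = n_null_sims,
                     seed = child_seed(seed, 1L))
      for (i in seq_len(nrow(fit$results))) {
        mm <- fit$results$method[i]
        out[[paste0("p_", mm)]] <- fit$results$p_value[i]
        out[[paste0("lambda_", mm)]] <- fit$results$lambda_hat[i]
        out[[paste0("h2_", mm)]] <- fit$results$heritability[i]
      }
      out$null_zero_mass <- fit$results$null_zero_mass[1]
    }
    y <- data$y
    if ("burden" %in% methods) {
      out$p_burden <- burden_test(y, proj, g_rare, w)$p_value
    }
    if ("SKAT" %in% methods) {
      out$p_SKAT <- skat_test(y, proj, g_rare, w)$p_value
    }
    if ("SKAT-O" %in% methods) {
      out[["p_SKAT-O"]] <- skat_o_test(y, proj, g_rare, w, n_mc = skato_n_mc,
                                       seed = child_seed(seed, 2L))$p_value
    }
    out
  }, error = function(e) {
    base$note <- if (inherits(e, "rvlrt_empty_set")) {
      "not testable: no rare variants"
    } else {
      paste("not testable:", conditionMessage(e))
    }
    base
  })
  res
}
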