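#' Configuration for the type-I-error / power study
#'
#' Captures every knob of the simulation study design: sample sizes with
#' their variant counts, significance levels, replicate counts, causal
#' architecture, methods, and seeds. The defaults reproduce the study
#' conditions: n in `{300, 400, 500}` with `{41, 47, 51}` rare variants,
#' alpha in `{0.01, 0.05}`, 2000 null replicates, 1000 power replicates,
#' 30% causal variants with effects `0.3 |log10 MAF|` of which 0/30/50%
#' are negative, and 2000 null simulations per (Re)LRT p-value.
#'
#' @param sample_sizes Sample sizes to study.
#' @param m_targets Rare-variant counts, one per sample size (default
#'   interpolates the calibration anchors 300:41, 400:47, 500:51).
#' @param alphas Nominal significance levels.
#' @param n_reps_null Replicates per type-I-error cell (>= 100).
#' @param n_reps_power Replicates per power cell (>= 100).
#' @param negative_fractions Fractions of causal effects with negative
#'   sign in the power study.
#' @param methods Methods to run; subset of `burden`, `SKAT`, `SKAT-O`,
#'   `LRT.K`, `ReLRT.K`, `LRT.M`, `ReLRT.M`.
#' @param n_null_sims Null-simulation size per (Re)LRT p-value (study
#'   default 2000: p floor 5e-4, adequate for alpha >= 0.01).
#' @param skato_n_mc Monte-Carlo size for SKAT-O minimum-p calibration.
#' @param causal_fraction,effect_c,noise_sd,covariate_betas,maf_range,sfs_alpha,haplotype_pool_size
#'   Generator settings, see [simulate_rv_dataset()].
#' @param fresh_genotypes Draw fresh genotypes each replicate (default) or
#'   reuse one panel per sample size.
#' @param seed Root seed; every replicate derives its own child seed, so
#'   serial and parallel runs agree.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return A `sim_study_config` list.
#' @export
sim_study_config <- function(sample_sizes = c(300, 400, 500),
                             m_targets = NULL,
                             alphas = c(0.01, 0.05),
                             n_reps_null = 2000,
                             n_reps_power = 1000,
                             negative_fractions = c(0, 0.3, 0.5),
                             methods = c("burden", "SKAT", "SKAT-O",
                                         "LRT.K", "ReLRT.K", "LRT.M", "ReLRT.M"),
                             n_null_sims = 2000,
                             skato_n_mc = 1000,
                             causal_fraction = 0.3, effect_c = 0.3,
                             noise_sd = 1, covariate_betas = c(0.5, 0.5),
                             maf_range = c(5e-4, 0.01), sfs_alpha = 1,
                             haplotype_pool_size = 500,
                             fresh_genotypes = TRUE,
                             seed = 1L, workers = 1L) {
  if (is.null(m_targets)) m_targets <- m_target_for_n(sample_sizes)
  stopifnot(length(m_targets) == length(sample_sizes),
            n_reps_null >= 100, n_reps_power >= 100)
  structure(as.list(environment()), class = "sim_study_config")
}

#' Rare-variant count for a given sample size
#'
#' Linear interpolation of the calibration anchors (300, 41), (400, 47),
#' (500, 51) used by the study design; constant extrapolation outside.
#'
#' @param n Sample size vector.
#' @return Integer vector of variant counts.
#' @export
m_target_for_n <- function(n) {
  round(stats::approx(c(300, 400, 500), c(41, 47, 51), xout = n, rule = 2)$y)
}

#' Run every configured method on one simulated dataset
#'
#' @param sim Dataset from [simulate_rv_dataset()].
#' @param methods Method names (see [sim_study_config()]).
#' @param n_null_sims,skato_n_mc,seed As in [sim_study_config()].
#' @return A tibble with columns `method`, `p_value`, `lambda_hat` (NA for
#'   score tests).
#' @export
run_methods_once <- function(sim, methods, n_null_sims = 2000,
                             skato_n_mc = 1000, seed = NULL) {
  seed <- seed %||% sample.int(2^31 - 2, 1)
  g <- sim$genotypes
  data <- sim$data
  w <- beta_maf_weights(g$variants$maf)$scaled
  proj <- null_projection(as.matrix(data[, c("x1", "x2")]))
  out <- list()
  vc_methods <- intersect(methods, c("LRT.M", "ReLRT.M", "LRT.K", "ReLRT.K"))
  if (length(vc_methods)) {
    fit <- vc_test(data, genotypes = g, pheno_col = "y",
                   covar_cols = c("x1", "x2"), methods = vc_methods,
                   weights = w, n_null_sims = n_null_sims, seed = seed)
    out$vc <- dplyr::select(fit$results, "method", "p_value", "lambda_hat")
  }
  y <- data$y
  if ("burden" %in% methods) {
    bt <- burden_test(y, proj, g, w)
    out$burden <- tibble::tibble(method = "burden", p_value = bt$p_value,
                                 lambda_hat = NA_real_)
  }
  if ("SKAT" %in% methods) {
    st <- skat_test(y, proj, g, w)
    out$skat <- tibble::tibble(method = "SKAT", p_value = st$p_value,
                               lambda_hat = NA_real_)
  }
  if ("SKAT-O" %in% methods) {
    so <- skat_o_test(y, proj, g, w, n_mc = skato_n_mc,
                      seed = child_seed(seed, 9L))
    out$skato <- tibble::tibble(method = "SKAT-O", p_value = so$p_value,
                                lambda_hat = NA_real_)
  }
  dplyr::bind_rows(out)
}

study_replicates <- function(cfg, n, m_target, n_reps, null,
                             negative_fraction, seed_block) {
  one_rep <- function(r) {
    rep_seed <- child_seed(cfg$seed, seed_block + r)
    sim <- simulate_rv_dataset(
      n = n, m_target = m_target, null = null,
      causal_fraction = cfg$causal_fraction, effect_c = cfg$effect_c,
      negative_fraction = negative_fraction,
      maf_range = cfg$maf_range, sfs_alpha = cfg$sfs_alpha,
      haplotype_pool_size = cfg$haplotype_pool_size,
      covariate_betas = cfg$covariate_betas, noise_sd = cfg$noise_sd,
      seed = if (cfg$fresh_genotypes) rep_seed else child_seed(cfg$seed, seed_block)
    )
    if (!cfg$fresh_genotypes) {
      # reuse the panel but refresh covariates/phenotype streams
      sim$data$y <- simulate_phenotype(
        sim$data[, c("x1", "x2")], sim$genotypes, sim$effects,
        cfg$covariate_betas, cfg$noise_sd, null = null,
        seed = child_seed(rep_seed, 4L)
      )
    }
    res <- run_methods_once(sim, cfg$methods, cfg$n_null_sims,
                            cfg$skato_n_mc, seed = child_seed(rep_seed, 5L))
    res$replicate <- r
    res
  }
  reps <- if (cfg$workers > 1L) {
    parallel::mclapply(seq_len(n_reps), one_rep, mc.cores = cfg$workers)
  } else {
    lapply(seq_len(n_reps), one_rep)
  }
  dplyr::bind_rows(reps)
}

#' Estimate type-I error for every configured method
#'
#' Per (sample size, method, alpha) cell: fresh surrogate genotypes per
#' replicate, a null phenotype (covariate effects plus unit Gaussian
#' noise, no genetic term), and the fraction of replicates with
#' `p < alpha`, with a binomial 95% confidence interval.
#'
#' @param cfg A [sim_study_config()].
#' @return A tibble of class `rv_study` (component `"type1"`): columns
#'   `n`, `method`, `alpha`, `rate`, `se`, `ci_lo`, `ci_hi`, `n_reps`.
#' @export
run_type1_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_study_config"))
  cells <- purrr::map2_dfr(cfg$sample_sizes, cfg$m_targets, function(n, m) {
    ps <- study_replicates(cfg, n, m, cfg$n_reps_null, null = TRUE,
                           negative_fraction = 0,
                           seed_block = 100000L * match(n, cfg$sample_sizes))
    tidyr::crossing(alpha = cfg$alphas,
                    dplyr::distinct(ps, .data$method)) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        rate = mean(ps$p_value[ps$method == .data$method] < .data$alpha),
        n_reps = sum(ps$method == .data$method)
      ) |>
      dplyr::ungroup() |>
      dplyr::mutate(n = n, .before = 1)
  })
  cells <- dplyr::mutate(
    cells,
    se = sqrt(.data$rate * (1 - .data$rate) / .data$n_reps),
    ci_lo = pmax(0, .data$rate - 1.96 * .data$se),
    ci_hi = pmin(1, .data$rate + 1.96 * .data$se)
  )
  structure(cells, class = c("rv_study", class(cells)),
            component = "type1", config = cfg)
}

#' Estimate power for every configured method
#'
#' Per (sample size, negative-effect fraction, method, alpha) cell:
#' alternative phenotypes with 30% causal rare variants, MAF-dependent
#' effects, and the configured fraction of negative signs; power is the
#' fraction of replicates with `p < alpha`.
#'
#' @param cfg A [sim_study_config()].
#' @return A tibble of class `rv_study` (component `"power"`): columns
#'   `n`, `negative_fraction`, `method`, `alpha`, `power`, `se`, `n_reps`.
#' @export
run_power_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_study_config"))
  grid <- tidyr::crossing(i = seq_along(cfg$sample_sizes),
                          negative_fraction = cfg$negative_fractions)
  cells <- purrr::pmap_dfr(grid, function(i, negative_fraction) {
    n <- cfg$sample_sizes[i]
    m <- cfg$m_targets[i]
    ps <- study_replicates(
      cfg, n, m, cfg$n_reps_power, null = FALSE,
      negative_fraction = negative_fraction,
      seed_block = 100000L * i + 10000000L * round(100 * negative_fraction)
    )
    tidyr::crossing(alpha = cfg$alphas, dplyr::distinct(ps, .data$method)) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        power = mean(ps$p_value[ps$method == .data$method] < .data$alpha),
        n_reps = sum(ps$method == .data$method)
      ) |>
      dplyr::ungroup() |>
      dplyr::mutate(n = n, negative_fraction = negative_fraction, .before = 1)
  })
  cells <- dplyr::mutate(cells,
                         se = sqrt(.data$power * (1 - .data$power) / .data$n_reps))
  structure(cells, class = c("rv_study", class(cells)),
            component = "power", config = cfg)
}

#' Power loss relative to the all-positive-effects setting
#'
#' For each method, sample size and alpha, the difference
#' `power(negative_fraction = 0) - power(negative_fraction = f)`, plus
#' the average across sample sizes.
#'
#' @param power_tbl Output of [run_power_study()] (must include
#'   `negative_fraction = 0`).
#' @return A tibble: `method`, `alpha`, `negative_fraction`, `n` (numeric
#'   or `"average"`), `loss`.
#' @export
power_loss <- function(power_tbl) {
  stopifnot(0 %in% power_tbl$negative_fraction)
  base <- dplyr::filter(power_tbl, .data$negative_fraction == 0) |>
    dplyr::select("n", "method", "alpha", base_power = "power")
  per_n <- power_tbl |>
    dplyr::filter(.data$negative_fraction > 0) |>
    dplyr::inner_join(base, by = c("n", "method", "alpha")) |>
    dplyr::mutate(loss = .data$base_power - .data$power) |>
    dplyr::select("method", "alpha", "negative_fraction", "n", "loss")
  avg <- per_n |>
    dplyr::group_by(.data$method, .data$alpha, .data$negative_fraction) |>
    dplyr::summarise(loss = mean(.data$loss), .groups = "drop") |>
    dplyr::mutate(n = NA_real_)
  dplyr::bind_rows(dplyr::mutate(per_n, n = as.numeric(.data$n)), avg) |>
    dplyr::arrange(.data$alpha, .data$negative_fraction, .data$method)
}

#' Plot a study report
#'
#' Type-I tables are drawn as rates with confidence intervals against the
#' nominal level; power tables as grouped bars by method, faceted on
#' sample size and negative-effect fraction.
#'
#' @param object An `rv_study` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rv_study <- function(object, ...) {
  comp <- attr(object, "component")
  if (identical(comp, "type1")) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$method, y = .data$rate)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi), width = 0.3) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                          linetype = 2) +
      ggplot2::facet_grid(alpha ~ n, scales = "free_y",
                          labeller = ggplot2::label_both) +
      ggplot2::labs(y = "empirical type-I error", x = NULL) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$method, y = .data$power,
                                 fill = factor(.data$negative_fraction))) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_grid(alpha ~ n, labeller = ggplot2::label_both) +
      ggplot2::labs(y = "empirical power", x = NULL,
                    fill = "negative fraction") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' Load a study configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [sim_study_config()]; unknown keys are rejected. Values given in the
#' file override the defaults, and callers can still override
#' programmatically via `...` (which wins over the file).
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `sim_study_config` list.
#' @export
sim_study_config_from_yaml <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read study configs")
  }
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_study_config)))
  if (length(unknown)) {
    stop("unknown study-config key(s): ", paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(sim_study_config, vals)
}

#' Write a study report as TSV plus a JSON twin
#'
#' @param report An `rv_study` tibble from [run_type1_study()] or
#'   [run_power_study()].
#' @param path Output TSV path; a `.json` twin with the same stem is
#'   written alongside for machine consumption (includes the root seed).
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  tab <- as.data.frame(report)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- attr(report, "config")
    twin <- list(component = attr(report, "component"),
                 seed = cfg$seed, cells = tab)
    jsonlite::write_json(twin, sub("\\.[^.]+$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
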