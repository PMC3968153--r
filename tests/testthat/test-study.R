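# Small-scale harness checks: the full study conditions run in
# test-acceptance.R; here the mechanics (determinism, parallel equality,
# report shape, qualitative monotonicity) are exercised at smoke scale.

smoke_cfg <- function(...) {
  sim_study_config(
    sample_sizes = 100, m_targets = 12, alphas = c(0.05, 1),
    n_reps_null = 100, n_reps_power = 100,
    negative_fractions = c(0, 0.5),
    methods = c("burden", "SKAT"), seed = 3L, ...
  )
}

test_that("type-I smoke run emits rates with confidence intervals", {
  rep1 <- run_type1_study(smoke_cfg())
  expect_true(all(c("n", "method", "alpha", "rate", "se", "ci_lo", "ci_hi",
                    "n_reps") %in% names(rep1)))
  expect_true(all(rep1$n_reps == 100))
  expect_true(all(rep1$rate >= 0 & rep1$rate <= 1))
  # alpha = 1 rejects everything
  expect_true(all(rep1$rate[rep1$alpha == 1] == 1))
  # nominal-level calibration at smoke scale, generous binomial band
  r05 <- rep1$rate[rep1$alpha == 0.05]
  expect_true(all(abs(r05 - 0.05) < 3 * sqrt(0.05 * 0.95 / 100) + 1e-9))
  p <- autoplot(rep1)
  expect_s3_class(p, "ggplot")
})

strip_study <- function(x) {
  attr(x, "config") <- NULL
  attr(x, "component") <- NULL
  as.data.frame(x)
}

test_that("study reruns with one seed reproduce every cell exactly", {
  expect_identical(strip_study(run_type1_study(smoke_cfg())),
                   strip_study(run_type1_study(smoke_cfg())))
})

test_that("parallel and serial execution give identical tables", {
  skip_on_os("windows")
  serial <- run_type1_study(smoke_cfg(workers = 1L))
  par2 <- run_type1_study(smoke_cfg(workers = 2L))
  # the stored config differs in the worker count; every cell must agree
  expect_identical(strip_study(serial), strip_study(par2))
})

test_that("power grows with effect size and the loss table is consistent", {
  cfg1 <- sim_study_config(sample_sizes = 150, m_targets = 12,
                           alphas = 0.05, n_reps_power = 120,
                           negative_fractions = c(0, 0.5),
                           methods = c("burden", "SKAT"),
                           effect_c = 0.3, seed = 9L)
  cfg2 <- sim_study_config(sample_sizes = 150, m_targets = 12,
                           alphas = 0.05, n_reps_power = 120,
                           negative_fractions = c(0, 0.5),
                           methods = c("burden", "SKAT"),
                           effect_c = 0.6, seed = 9L)
  pw1 <- run_power_study(cfg1)
  pw2 <- run_power_study(cfg2)
  joined <- dplyr::inner_join(
    tibble::as_tibble(pw1), tibble::as_tibble(pw2),
    by = c("n", "negative_fraction", "method", "alpha"),
    suffix = c("_c03", "_c06")
  )
  # doubled effects: power non-decreasing in every cell (up to MC noise)
  expect_true(all(joined$power_c06 >= joined$power_c03 - 0.05))
  loss <- power_loss(pw2)
  expect_true(all(c("method", "alpha", "negative_fraction", "n", "loss")
                  %in% names(loss)))
  # per-n rows plus one averaged row per method
  expect_equal(sum(is.na(loss$n)), 2L)
  avg <- loss[is.na(loss$n), ]
  per_n <- loss[!is.na(loss$n), ]
  for (mm in avg$method) {
    expect_equal(avg$loss[avg$method == mm],
                 mean(per_n$loss[per_n$method == mm]))
  }
  expect_s3_class(autoplot(pw2), "ggplot")
})

test_that("YAML study configs mirror the constructor and reject unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("sample_sizes: [300]", "m_targets: [41]", "n_reps_null: 200",
               "methods: [SKAT]", "seed: 7"), path)
  cfg <- sim_study_config_from_yaml(path, n_reps_null = 250)
  expect_s3_class(cfg, "sim_study_config")
  expect_equal(cfg$sample_sizes, 300)
  expect_equal(cfg$m_targets, 41)
  expect_equal(cfg$n_reps_null, 250) # programmatic override wins
  expect_equal(cfg$seed, 7)
  writeLines("not_a_knob: 1", path)
  expect_error(sim_study_config_from_yaml(path), "unknown study-config key")
})

test_that("study reports are written as TSV with a JSON twin", {
  rep1 <- run_type1_study(smoke_cfg())
  path <- file.path(tempdir(), "type1.tsv")
  write_study_report(rep1, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(rep1))
  twin <- jsonlite::read_json(file.path(tempdir(), "type1.json"))
  expect_equal(twin$component, "type1")
  expect_equal(twin$seed, 3)
  expect_equal(length(twin$cells), nrow(rep1))
})
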