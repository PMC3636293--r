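test_that("generated trials honour the configured design exactly", {
  cfg <- trial_config(seed = 7L)
  trial <- generate_trial(cfg)

  base <- trial[trial$wave == 1, ]
  expect_equal(nrow(base), 414L)
  expect_equal(as.vector(table(base$arm)[arm_levels()]),
               unname(cfg$arm_sizes[arm_levels()]))
  expect_equal(nrow(trial), 414L * length(cfg$wave_times))

  # determinism: same config, byte-identical tables
  expect_identical(trial, generate_trial(cfg))
  # a different seed moves the data
  expect_false(identical(trial, generate_trial(trial_config(seed = 8L))))

  # schema invariants
  expect_silent(validate_trial(trial))
  expect_true(all(as.matrix(trial[eq5d_items()]) %in% 1:3))
  expect_true(all(trial$smoking_status %in% 1:2))
  expect_true(all(trial$ftnd >= 0 & trial$ftnd <= 10))
  expect_true(all(as.matrix(trial[cost_categories()]) >= 0))
})

test_that("degenerate abstinence probabilities give zero abstainers", {
  cfg <- trial_config(abstinence_probs = c(MTC = 0, MT = 0, UC = 0), seed = 3L)
  trial <- generate_trial(cfg)
  final <- trial[trial$wave == max(trial$wave), ]
  expect_equal(sum(final$smoking_status == 2L), 0L)
})

test_that("per-arm abstinence rates sit inside the binomial 95% interval", {
  cfg <- trial_config(seed = 21L)
  trial <- generate_trial(cfg)
  final <- trial[trial$wave == max(trial$wave), ]
  for (a in arm_levels()) {
    k <- sum(final$smoking_status[final$arm == a] == 2L)
    n <- cfg$arm_sizes[[a]]
    ci <- stats::binom.test(k, n)$conf.int
    expect_gte(cfg$abstinence_probs[[a]], ci[1])
    expect_lte(cfg$abstinence_probs[[a]], ci[2])
  }
})

test_that("generated costs are right-skewed when dispersion is positive", {
  cfg <- trial_config(seed = 5L)
  trial <- generate_trial(cfg)
  prices <- default_unit_prices()
  costs <- value_costs(trial, prices)$healthcare_cost
  skew <- mean((costs - mean(costs))^3) / stats::sd(costs)^3
  expect_gt(skew, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(arm_sizes = c(MTC = 0L, MT = 1L, UC = 1L)),
               "positive")
  expect_error(trial_config(abstinence_probs = c(MTC = 1.2, MT = 0, UC = 0)),
               "probabilities")
  expect_error(trial_config(wave_times = c(0, 0.5, 0.5, 1)), "increasing")
  expect_error(trial_config(wave_times = c(0.1, 0.5, 1)), "start at 0")
  expect_error(trial_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(trial_config(cost_dispersion = -1), "cost_dispersion")
})

test_that("zero dropout leaves the table untouched", {
  cfg <- trial_config(dropout_rate = 0, seed = 2L)
  trial <- generate_trial(cfg)
  expect_identical(apply_missingness(trial, cfg), trial)
})

test_that("missingness is monotone and baseline is never missing", {
  cfg <- trial_config(seed = 13L)
  trial <- apply_missingness(generate_trial(cfg), cfg)
  expect_false(anyNA(trial[trial$wave == 1,
                           c(cost_categories(), eq5d_items(),
                             "smoking_status", "ftnd")]))
  miss <- tapply(is.na(trial$smoking_status), trial$id,
                 function(m) all(diff(m) >= 0))
  expect_true(all(miss))
})

test_that("marginal 12-month retention matches the configured dropout rate", {
  cfg <- trial_config(seed = 1L)
  trial <- generate_trial(cfg)
  retained <- vapply(1:200, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- s
    tm <- apply_missingness(trial, cfg_s)
    mean(!is.na(tm$smoking_status[tm$wave == max(tm$wave)]))
  }, numeric(1))
  expect_lt(abs(mean(retained) - (1 - 0.442)), 0.02)
})

test_that("dropout concentrates among younger participants", {
  cfg <- trial_config(seed = 1L)
  trial <- generate_trial(cfg)
  base <- trial[trial$wave == 1, ]
  gap <- vapply(1:100, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- s
    tm <- apply_missingness(trial, cfg_s)
    dropped <- is.na(tm$smoking_status[tm$wave == max(tm$wave)])
    mean(base$age[!dropped]) - mean(base$age[dropped])
  }, numeric(1))
  expect_gt(mean(gap), 0)
})

test_that("trial CSV round-trips through write and read", {
  cfg <- trial_config(arm_sizes = c(MTC = 5L, MT = 4L, UC = 3L), seed = 9L)
  trial <- apply_missingness(generate_trial(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(trial, path)
  back <- read_trial_csv(path)
  expect_equal(back$smoking_status, trial$smoking_status)
  expect_equal(back[cost_categories()], trial[cost_categories()],
               ignore_attr = TRUE)
  expect_equal(as.character(back$arm), as.character(trial$arm))
})
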