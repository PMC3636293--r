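test_that("incremental ratios and dominance classes follow the plane signs", {
  r <- incremental(list(cost = 255, effect = 0.05), list(cost = 0, effect = 0))
  expect_equal(r$ratio, 5100)
  expect_equal(r$class, "tradeoff_NE")

  r2 <- incremental(list(cost = 806, effect = -0.02), list(cost = 0, effect = 0))
  expect_equal(r2$class, "dominated")
  expect_equal(r2$ratio, -40300)

  r3 <- incremental(list(cost = -10, effect = 0.01), list(cost = 0, effect = 0))
  expect_equal(r3$class, "dominant")

  r4 <- incremental(list(cost = -10, effect = -0.01), list(cost = 0, effect = 0))
  expect_equal(r4$class, "tradeoff_SW")

  same <- list(cost = 100, effect = 0.5)
  r5 <- incremental(same, same)
  expect_equal(r5$delta_cost, 0)
  expect_equal(r5$delta_effect, 0)
  expect_true(is.na(r5$ratio))
  expect_equal(r5$class, "equivalent")

  # zero effect difference: classified by cost alone, ratio undefined
  r6 <- incremental(list(cost = 50, effect = 0.5), list(cost = 0, effect = 0.5))
  expect_true(is.na(r6$ratio))
  expect_equal(r6$class, "dominated")
})

test_that("the ratio is direction-blind but the class flips with the signs", {
  set.seed(5)
  for (i in 1:20) {
    dc <- rnorm(1, 0, 500)
    de <- rnorm(1, 0, 0.1)
    a <- incremental(list(cost = dc, effect = de), list(cost = 0, effect = 0))
    b <- incremental(list(cost = 0, effect = 0), list(cost = dc, effect = de))
    expect_equal(a$ratio, b$ratio)
    flips <- c(dominant = "dominated", dominated = "dominant",
               tradeoff_NE = "tradeoff_SW", tradeoff_SW = "tradeoff_NE")
    expect_equal(b$class, unname(flips[a$class]))
  }
})

test_that("net monetary benefit is effects monetized minus costs", {
  expect_equal(nmb(0.05, 255, 18000), 645)
  expect_equal(nmb(0.3, 120, 0), -120)
  expect_equal(nmb(0, 0, c(0, 1e4, 1e5)), c(0, 0, 0))
  expect_error(nmb(0.1, 10, -5), "wtp")
})

test_that("stratified bootstrap preserves arm sizes and is seed-stable", {
  out <- participant_outcomes(toy_trial(n_per_arm = 3), flat_prices())
  reps <- bootstrap_arms(out, n_reps = 50, seed = 4L)
  expect_equal(reps$arms, arm_levels())
  expect_equal(dim(reps$total_cost), c(50L, 3L))
  expect_identical(reps$total_cost,
                   bootstrap_arms(out, n_reps = 50, seed = 4L)$total_cost)

  # resampling a singleton arm reproduces the observed summary
  out1 <- participant_outcomes(toy_trial(n_per_arm = 1, counts = 2),
                               flat_prices())
  reps1 <- bootstrap_arms(out1, n_reps = 1, seed = 1L)
  expect_equal(reps1$total_cost[1, ], setNames(
    arm_summaries(out1)$mean_cost, arm_levels()))

  # identical participants: all replicates identical
  repsC <- bootstrap_arms(out, n_reps = 20, seed = 2L)
  expect_equal(apply(repsC$total_cost, 2, stats::sd),
               setNames(c(0, 0, 0), arm_levels()))
})

test_that("percentile intervals are empirical quantiles", {
  expect_equal(percentile_ci(rep(3.5, 10)), c(lower = 3.5, upper = 3.5))
  expect_equal(percentile_ci(1:1000, 0.95),
               c(lower = 25.975, upper = 975.025))
  x <- c(-(50:1), 50:1)  # symmetric about 0
  ci <- percentile_ci(x, 0.9)
  expect_equal(ci[["lower"]], -ci[["upper"]])
  expect_error(percentile_ci(1), "2 replicates")
  expect_error(percentile_ci(1:10, 1.5), "level")
})

test_that("bootstrap percentile CI brackets the analytic mean of 1..100", {
  out <- data.frame(id = 1:200, arm = rep(c("MT", "UC"), each = 100),
                    total_cost = c(1:100, 1:100), abstinent = 0,
                    qaly = 0.5)
  reps <- bootstrap_arms(out, n_reps = 5000, seed = 6L)
  ci <- percentile_ci(reps$total_cost[, "MT"], 0.95)
  expect_lt(ci[["lower"]], 50.5)
  expect_gt(ci[["upper"]], 50.5)
  # and the replicate mean is close to the sample mean
  expect_lt(abs(mean(reps$total_cost[, "MT"]) - 50.5), 1)
})

test_that("acceptability curves are proper probabilities with the WTP=0 limit", {
  cfg <- trial_config(arm_sizes = c(MTC = 40L, MT = 40L, UC = 40L), seed = 19L)
  out <- participant_outcomes(generate_trial(cfg))
  reps <- bootstrap_arms(out, n_reps = 300, seed = 3L)
  grid <- seq(0, 100000, by = 5000)
  curve <- ceac(reps, grid, "abstinent")
  probs <- as.matrix(curve[paste0("p_", arm_levels())])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, length(grid)))

  # WTP = 0: probability of having the lowest mean cost
  lowest <- table(factor(arm_levels()[apply(reps$total_cost, 1, which.min)],
                         levels = arm_levels())) / reps$n_reps
  expect_equal(unname(probs[1, ]), as.vector(lowest))
})

test_that("exact NMB ties are split equally among tied arms", {
  out <- participant_outcomes(toy_trial(n_per_arm = 2), flat_prices())
  out$total_cost <- 100  # equalize programme costs: arms fully degenerate
  reps <- bootstrap_arms(out, n_reps = 10, seed = 1L)
  curve <- ceac(reps, c(0, 18000), "abstinent")  # all arms identical
  expect_equal(unname(as.matrix(curve[paste0("p_", arm_levels())])),
               matrix(1 / 3, 2, 3))
})

test_that("an arm dominant in every replicate gets probability one at all WTP", {
  out <- participant_outcomes(toy_trial(n_per_arm = 2), flat_prices())
  out$total_cost[out$arm == "MT"] <- out$total_cost[out$arm == "MT"] - 100
  out$abstinent[out$arm == "MT"] <- 1L
  reps <- bootstrap_arms(out, n_reps = 25, seed = 2L)
  curve <- ceac(reps, seq(0, 50000, 10000), "abstinent")
  expect_equal(curve$p_MT, rep(1, 6))
})

test_that("NMB ranking is invariant to common cost or effect shifts", {
  set.seed(23)
  reps <- structure(list(
    total_cost = matrix(rnorm(60, 1000, 100), 20, 3,
                        dimnames = list(NULL, arm_levels())),
    abstinent = matrix(runif(60), 20, 3, dimnames = list(NULL, arm_levels())),
    qaly = matrix(runif(60), 20, 3, dimnames = list(NULL, arm_levels())),
    arms = arm_levels(), n_reps = 20L), class = "boot_reps")
  grid <- seq(0, 40000, 2000)
  base <- ceac(reps, grid, "abstinent")
  shifted <- reps
  shifted$total_cost <- reps$total_cost + 500
  shifted$abstinent <- reps$abstinent + 0.1
  expect_equal(ceac(shifted, grid, "abstinent"), base)
})

test_that("evaluate is deterministic and its sensitivity scenario shifts
           programme costs by the patient-cost increments", {
  cfg_t <- trial_config(arm_sizes = c(MTC = 25L, MT = 20L, UC = 20L),
                        seed = 29L)
  trial <- generate_trial(cfg_t)
  cfg <- analysis_config(seed = 8L, n_reps_costs = 200L, n_reps_ceac = 100L,
                         wtp_grid = seq(0, 40000, 10000))
  res <- evaluate(trial, config = cfg)
  res2 <- evaluate(trial, config = cfg)
  expect_equal(res, res2)

  sens <- res$sensitivity
  expect_equal(sens$config$scenario, "sensitivity")
  d_primary <- res$incrementals
  d_sens <- sens$incrementals
  delta <- d_sens$delta_cost - d_primary$delta_cost
  names(delta) <- d_primary$label
  expect_equal(delta[["MTC vs UC"]], 141.89 - 57.70)   # 84.19
  expect_equal(delta[["MT vs UC"]], 82.24 - 7.70)      # 74.54
  expect_equal(delta[["MTC vs MT"]], 84.19 - 74.54)
  # effects are untouched by the cost scenario
  expect_equal(d_sens$delta_effect, d_primary$delta_effect)
})

test_that("configured zero effect contrasts leave the CEAC cost-driven", {
  cfg_t <- trial_config(arm_sizes = c(MTC = 30L, MT = 30L, UC = 30L),
                        abstinence_probs = c(MTC = 0, MT = 0, UC = 0),
                        seed = 41L)
  out <- participant_outcomes(generate_trial(cfg_t))
  reps <- bootstrap_arms(out, n_reps = 200, seed = 5L)
  curve <- ceac(reps, c(0, 20000, 80000), "abstinent")
  probs <- as.matrix(curve[paste0("p_", arm_levels())])
  # zero effect everywhere: the curve equals its own WTP=0 (cost-only) limit
  expect_equal(probs[2, ], probs[1, ])
  expect_equal(probs[3, ], probs[1, ])
})
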