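# Incremental cost-effectiveness / cost-utility analysis: ICER and ICUR with
# dominance classification, net monetary benefit, stratified nonparametric
# bootstrap, percentile confidence intervals, and acceptability curves.

#' Per-participant analysis outcomes
#'
#' Joins the annual cost profile, the 12-month abstinence indicator (status 2
#' at the final wave) and the QALY into one row per participant — the unit
#' that is resampled by the bootstrap.
#'
#' @param trial complete (imputed) participant table.
#' @param prices unit-price data.frame.
#' @param scenario cost scenario (`"primary"` or `"sensitivity"`).
#' @param value_set EQ-5D value set.
#' @param auc_method QALY accumulation rule.
#' @param cpi_from,cpi_to price-index pair.
#' @return data.frame: id, arm, healthcare_cost, intervention_cost,
#'   total_cost, abstinent (0/1), qaly.
#' @export
participant_outcomes <- function(trial, prices = default_unit_prices(),
                                 scenario = "primary",
                                 value_set = dutch_tariff_3l(),
                                 auc_method = "trapezoid",
                                 cpi_from = 105.38, cpi_to = 109.02) {
  costs <- value_costs(trial, prices, scenario, cpi_from, cpi_to)
  qalys <- compute_qalys(trial, value_set, auc_method)
  last_wave <- max(trial$wave)
  fin <- trial[trial$wave == last_wave, c("id", "smoking_status")]
  out <- costs[, c("id", "arm", "healthcare_cost", "intervention_cost",
                   "total_cost")]
  out$abstinent <- as.integer(fin$smoking_status[match(out$id, fin$id)] == 2L)
  out$qaly <- qalys$qaly[match(out$id, qalys$id)]
  out
}

#' Per-arm mean costs and effects
#'
#' @param outcomes data.frame from \code{\link{participant_outcomes}}.
#' @return data.frame, one row per arm: n, mean_healthcare_cost, mean_cost
#'   (total, including intervention), p_abstinent, mean_qaly.
#' @export
arm_summaries <- function(outcomes) {
  arms <- intersect(arm_levels(), unique(as.character(outcomes$arm)))
  do.call(rbind, lapply(arms, function(a) {
    x <- outcomes[outcomes$arm == a, ]
    data.frame(arm = a, n = nrow(x),
               mean_healthcare_cost = mean(x$healthcare_cost, na.rm = TRUE),
               mean_cost = mean(x$total_cost, na.rm = TRUE),
               p_abstinent = mean(x$abstinent, na.rm = TRUE),
               mean_qaly = mean(x$qaly, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Incremental cost-effectiveness (or cost-utility) ratio with dominance
#'
#' Computes the incremental cost and effect of a treatment over a reference,
#' the ratio `(C_i - C_c) / (E_i - E_c)` when the effect difference is
#' non-zero, and the cost-effectiveness-plane class: `dominant` (cheaper and
#' more effective), `dominated` (costlier and less effective),
#' `tradeoff_NE` (costlier, more effective), `tradeoff_SW` (cheaper, less
#' effective).
#'
#' @param treat,ref lists or one-row data.frames with elements/columns
#'   `cost` and `effect` (effects on the same scale for both).
#' @param label comparison label (default built from `arm` fields if
#'   present).
#' @return data.frame: label, delta_cost, delta_effect, ratio (NA when
#'   the effect difference is 0), class.
#' @export
incremental <- function(treat, ref, label = NULL) {
  if (is.null(label)) {
    a1 <- if (!is.null(treat$arm)) as.character(treat$arm) else "treat"
    a2 <- if (!is.null(ref$arm)) as.character(ref$arm) else "ref"
    label <- paste(a1, "vs", a2)
  }
  dc <- treat$cost - ref$cost
  de <- treat$effect - ref$effect
  ratio <- if (de != 0) dc / de else NA_real_
  cls <- if (de > 0 && dc < 0) "dominant"
  else if (de < 0 && dc > 0) "dominated"
  else if (de > 0 && dc >= 0) "tradeoff_NE"
  else if (de < 0 && dc <= 0) "tradeoff_SW"
  else if (dc > 0) "dominated"   # de == 0: classify by cost alone
  else if (dc < 0) "dominant"
  else "equivalent"
  data.frame(label = label, delta_cost = dc, delta_effect = de,
             ratio = ratio, class = cls, stringsAsFactors = FALSE)
}

#' Net monetary benefit
#'
#' `NMB = delta_effect * wtp - delta_cost`: incremental effects monetized at
#' the willingness-to-pay threshold, minus incremental costs. Vectorized.
#'
#' @param delta_effect incremental effect (probability of abstinence or
#'   QALYs).
#' @param delta_cost incremental euro cost.
#' @param wtp willingness to pay per effect unit (>= 0).
#' @return Euro net monetary benefit.
#' @export
nmb <- function(delta_effect, delta_cost, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  delta_effect * wtp - delta_cost
}

#' Stratified nonparametric bootstrap of arm summaries
#'
#' Resamples participants with replacement within each arm (preserving the
#' randomized arm sizes) and recomputes per-arm mean total cost, abstinence
#' probability and mean QALY for every replicate. Deterministic given the
#' seed.
#'
#' @param outcomes data.frame from \code{\link{participant_outcomes}}.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param stats names of outcome columns to average per replicate.
#' @return List of class `boot_reps`: one `n_reps` x `n_arms` matrix per
#'   statistic (named as in `stats`), plus `arms` and `n_reps`.
#' @export
bootstrap_arms <- function(outcomes, n_reps, seed = 1L,
                           stats = c("total_cost", "abstinent", "qaly")) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  arms <- intersect(arm_levels(), unique(as.character(outcomes$arm)))
  if (length(arms) < 1) stop("no arms in outcomes", call. = FALSE)
  set.seed(as.integer(seed))
  res <- lapply(stats, function(s) matrix(NA_real_, n_reps, length(arms),
                                          dimnames = list(NULL, arms)))
  names(res) <- stats
  for (a in arms) {
    rows <- which(outcomes$arm == a)
    n <- length(rows)
    if (n == 0) stop("empty arm: ", a, call. = FALSE)
    idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
    for (s in stats) {
      x <- outcomes[[s]][rows]
      res[[s]][, a] <- colMeans(matrix(x[idx], nrow = n))
    }
  }
  structure(c(res, list(arms = arms, n_reps = n_reps)), class = "boot_reps")
}

#' Percentile bootstrap confidence interval
#'
#' Empirical percentile interval of a scalar statistic's bootstrap
#' replicates: for `level = 0.95`, the 2.5th and 97.5th percentiles
#' (linear-interpolation quantiles).
#'
#' @param replicates numeric vector of bootstrap replicates (length >= 2).
#' @param level confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(replicates, level = 0.95) {
  if (length(replicates) < 2) stop("need at least 2 replicates", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  q <- quantile(replicates, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each arm attains
#' the highest net monetary benefit across bootstrap replicates (per-arm
#' `E * wtp - C`; the common reference cancels when comparing arms). Exact
#' ties are split equally among the tied arms, so probabilities sum to 1 at
#' every threshold.
#'
#' @param reps `boot_reps` from \code{\link{bootstrap_arms}}.
#' @param wtp_grid non-empty vector of willingness-to-pay values.
#' @param effect which effect statistic to use (`"abstinent"` for the CEAC,
#'   `"qaly"` for the cost-utility curve).
#' @return data.frame of class `ceac_curve`: column `wtp` plus one
#'   probability column per arm (`p_MTC`, `p_MT`, `p_UC`).
#' @export
ceac <- function(reps, wtp_grid, effect = c("abstinent", "qaly")) {
  effect <- match.arg(effect)
  if (length(wtp_grid) < 1) stop("wtp_grid must be non-empty", call. = FALSE)
  arms <- reps$arms
  if (length(arms) < 2) stop("need at least 2 arms", call. = FALSE)
  E <- reps[[effect]]
  C <- reps$total_cost
  out <- matrix(0, length(wtp_grid), length(arms),
                dimnames = list(NULL, paste0("p_", arms)))
  for (g in seq_along(wtp_grid)) {
    b <- E * wtp_grid[g] - C
    best <- b == apply(b, 1, max)
    share <- best / rowSums(best)       # ties split equally
    out[g, ] <- colMeans(share)
  }
  res <- data.frame(wtp = wtp_grid, out)
  class(res) <- c("ceac_curve", "data.frame")
  res
}

pairwise_incrementals <- function(summ, effect_col, cost_col = "mean_cost") {
  pairs <- list(c("MT", "UC"), c("MTC", "UC"), c("MTC", "MT"))
  do.call(rbind, lapply(pairs, function(p) {
    t <- summ[summ$arm == p[1], ]
    r <- summ[summ$arm == p[2], ]
    incremental(list(arm = p[1], cost = t[[cost_col]], effect = t[[effect_col]]),
                list(arm = p[2], cost = r[[cost_col]], effect = r[[effect_col]]))
  }))
}

#' Full trial-based economic evaluation
#'
#' Orchestrates the evaluation on a complete (imputed) participant table:
#' arm summaries, pairwise incremental cost-effectiveness (abstinence) and
#' cost-utility (QALY) results, bootstrap percentile intervals for pairwise
#' annual-cost differences, acceptability curves on both effect scales, the
#' probability-of-highest-NMB table at the configured threshold, and a rerun
#' under the sensitivity programme-cost scenario.
#'
#' @param trial complete (imputed) participant table.
#' @param prices unit-price data.frame.
#' @param config an \code{\link{analysis_config}}.
#' @param value_set EQ-5D value set.
#' @return List of class `cea_results` with elements `arm_summaries`,
#'   `incrementals` (both scales), `cost_cis`, `ceac`, `cuac`,
#'   `probabilities_at_wtp`, `config`, and (for the primary scenario)
#'   `sensitivity`, the same bundle under inflated programme costs.
#' @export
evaluate <- function(trial, prices = default_unit_prices(),
                     config = analysis_config(),
                     value_set = dutch_tariff_3l()) {
  outcomes <- participant_outcomes(
    trial, prices, scenario = config$scenario, value_set = value_set,
    auc_method = config$auc_method,
    cpi_from = config$cpi_from, cpi_to = config$cpi_to)

  summ <- arm_summaries(outcomes)
  incr <- rbind(
    cbind(outcome = "prolonged_abstinence",
          pairwise_incrementals(summ, "p_abstinent")),
    cbind(outcome = "qaly",
          pairwise_incrementals(summ, "mean_qaly")))

  cost_reps <- bootstrap_arms(outcomes, config$n_reps_costs,
                              derive_seed(config$seed, "cost-bootstrap"),
                              stats = "total_cost")
  pairs <- list(c("MTC", "MT"), c("UC", "MT"), c("MTC", "UC"))
  cost_cis <- do.call(rbind, lapply(pairs, function(p) {
    d <- cost_reps$total_cost[, p[1]] - cost_reps$total_cost[, p[2]]
    ci <- percentile_ci(d, 0.95)
    data.frame(comparison = paste0(p[1], "-", p[2]),
               mean_diff = summ$mean_cost[summ$arm == p[1]] -
                 summ$mean_cost[summ$arm == p[2]],
               lower = ci[["lower"]], upper = ci[["upper"]],
               stringsAsFactors = FALSE)
  }))

  ceac_reps <- bootstrap_arms(outcomes, config$n_reps_ceac,
                              derive_seed(config$seed, "ceac-bootstrap"))
  cea_curve <- ceac(ceac_reps, config$wtp_grid, "abstinent")
  cua_curve <- ceac(ceac_reps, config$wtp_grid, "qaly")

  at_wtp <- rbind(
    cbind(outcome = "prolonged_abstinence",
          ceac(ceac_reps, config$wtp_threshold, "abstinent")),
    cbind(outcome = "qaly",
          ceac(ceac_reps, config$wtp_threshold, "qaly")))

  res <- list(arm_summaries = summ, incrementals = incr, cost_cis = cost_cis,
              ceac = cea_curve, cuac = cua_curve,
              probabilities_at_wtp = at_wtp, config = config)
  if (config$scenario == "primary") {
    sens_cfg <- config
    sens_cfg$scenario <- "sensitivity"
    res$sensitivity <- evaluate(trial, prices, sens_cfg, value_set)
  }
  class(res) <- "cea_results"
  res
}

#' @export
print.cea_results <- function(x, ...) {
  cat("Trial-based economic evaluation (", x$config$scenario,
      " scenario)\n\n", sep = "")
  cat("Arm summaries:\n")
  print(transform(x$arm_summaries,
                  mean_healthcare_cost = round(mean_healthcare_cost, 2),
                  mean_cost = round(mean_cost, 2),
                  p_abstinent = round(p_abstinent, 3),
                  mean_qaly = round(mean_qaly, 3)), row.names = FALSE)
  cat("\nIncremental results (ratio = euro per effect unit):\n")
  print(transform(x$incrementals, delta_cost = round(delta_cost, 2),
                  delta_effect = round(delta_effect, 3),
                  ratio = round(ratio)), row.names = FALSE)
  cat("\nProbability of highest net monetary benefit at WTP ",
      x$config$wtp_threshold, ":\n", sep = "")
  print(transform(x$probabilities_at_wtp), row.names = FALSE)
  invisible(x)
}
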