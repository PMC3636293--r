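#' Synthetic trial configuration
#'
#' Defines the statistical structure of a simulated three-arm smoking-cessation
#' trial: arm sizes, 12-month prolonged-abstinence probabilities, the baseline
#' utility targeted by the EQ-5D item generator, per-category mean health-care
#' costs per 3-month recall window, cost overdispersion, and an age-dependent
#' monotone dropout process.
#'
#' Defaults reproduce the design of a Dutch general-practice cessation trial:
#' 163/132/119 participants (MTC/MT/UC), prolonged abstinence .086/.152/.101,
#' baseline utility 0.8 (SD 0.2), right-skewed costs, 44.2% loss to follow-up
#' concentrated among younger participants, and measurement waves at baseline,
#' 6 weeks, 6 months and 12 months.
#'
#' @param arm_sizes named integer vector (MTC, MT, UC), all > 0.
#' @param abstinence_probs named probability vector per arm, in [0, 1].
#' @param utility_mean,utility_sd target mean and spread of scored baseline
#'   utility (unitless, utilities capped at 1).
#' @param cost_means matrix (category x arm) of mean euro cost per 3-month
#'   recall window; rownames must be `cost_categories()`, colnames
#'   `arm_levels()`.
#' @param cost_dispersion negative-binomial overdispersion of resource-use
#'   counts (0 = Poisson; larger = heavier tail).
#' @param dropout_rate marginal probability of loss to follow-up by 12 months.
#' @param dropout_age_coefficient log-odds of dropout per year of age
#'   (negative: younger participants drop out more).
#' @param wave_times measurement times in years from baseline, strictly
#'   increasing, starting at 0.
#' @param recall_years length of the retrospective costing window (years).
#' @param seed integer seed; generation is deterministic given the config.
#' @return A validated list of class `trial_config`.
#' @export
trial_config <- function(arm_sizes = c(MTC = 163L, MT = 132L, UC = 119L),
                         abstinence_probs = c(MTC = 0.086, MT = 0.152, UC = 0.101),
                         utility_mean = 0.8,
                         utility_sd = 0.2,
                         cost_means = default_cost_means(),
                         cost_dispersion = 1.5,
                         dropout_rate = 0.442,
                         dropout_age_coefficient = -0.05,
                         wave_times = c(0, 0.115, 0.5, 1),
                         recall_years = 0.25,
                         seed = 1L) {
  cfg <- list(arm_sizes = arm_sizes, abstinence_probs = abstinence_probs,
              utility_mean = utility_mean, utility_sd = utility_sd,
              cost_means = cost_means, cost_dispersion = cost_dispersion,
              dropout_rate = dropout_rate,
              dropout_age_coefficient = dropout_age_coefficient,
              wave_times = wave_times, recall_years = recall_years,
              seed = as.integer(seed))
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid trial_config: ", msg, call. = FALSE)
  a <- cfg$arm_sizes
  if (length(a) != 3L || is.null(names(a)) || !setequal(names(a), arm_levels()))
    stop_cfg("arm_sizes must be named MTC, MT, UC")
  if (any(!is.finite(a)) || any(a <= 0) || any(a != round(a)))
    stop_cfg("arm_sizes must be positive integers")
  p <- cfg$abstinence_probs
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_cfg("abstinence_probs must be probabilities in [0, 1]")
  if (!is.matrix(cfg$cost_means) ||
      !identical(rownames(cfg$cost_means), cost_categories()) ||
      !setequal(colnames(cfg$cost_means), arm_levels()))
    stop_cfg("cost_means must be a category x arm matrix")
  if (any(cfg$cost_means < 0)) stop_cfg("cost_means must be non-negative")
  if (!is.finite(cfg$cost_dispersion) || cfg$cost_dispersion < 0)
    stop_cfg("cost_dispersion must be >= 0")
  if (!is.finite(cfg$dropout_rate) || cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stop_cfg("dropout_rate must be in [0, 1]")
  w <- cfg$wave_times
  if (length(w) < 2L || w[1] != 0 || any(diff(w) <= 0))
    stop_cfg("wave_times must be strictly increasing and start at 0")
  if (!is.finite(cfg$utility_mean) || cfg$utility_mean <= 0 || cfg$utility_mean > 1)
    stop_cfg("utility_mean must be in (0, 1]")
  if (!is.finite(cfg$utility_sd) || cfg$utility_sd <= 0)
    stop_cfg("utility_sd must be > 0")
  if (!is.finite(cfg$recall_years) || cfg$recall_years <= 0 || cfg$recall_years > 1)
    stop_cfg("recall_years must be in (0, 1]")
  invisible(cfg)
}

#' Default per-window mean costs (euro per category per arm per 3 months)
#'
#' Calibrated to the baseline 3-month health-care cost profile of the
#' reference trial (GP consultations and hospital admissions dominating the
#' mean and the variance respectively).
#' @return Numeric matrix, `cost_categories()` by `arm_levels()`.
#' @export
default_cost_means <- function() {
  m <- cbind(
    MTC = c(53.2, 65.4, 206.9, 5.1, 30.3, 26.7, 1.7, 26.0),
    MT  = c(61.0, 78.6,  50.9, 9.4, 24.3, 36.4, 3.4, 19.2),
    UC  = c(49.7, 87.6,  47.9, 4.9, 38.2, 13.6, 1.9, 12.5))
  rownames(m) <- cost_categories()
  m
}

#' Analysis configuration for the economic evaluation
#'
#' @param wtp_threshold willingness-to-pay threshold (euro per effect unit) at
#'   which headline net-monetary-benefit probabilities are reported. Default
#'   18000, the accepted Dutch cutoff per QALY.
#' @param wtp_grid grid of willingness-to-pay values for acceptability curves.
#' @param n_reps_costs bootstrap replicates for cost confidence intervals.
#' @param n_reps_ceac bootstrap replicates for acceptability curves.
#' @param seed root seed; all bootstrap substreams are derived from it.
#' @param scenario `"primary"` (programme costs only) or `"sensitivity"`
#'   (programme costs including monetised patient time and travel).
#' @param auc_method QALY accumulation rule, `"trapezoid"` or `"rectangle"`.
#' @param cpi_from,cpi_to consumer price indices for price-year indexing
#'   (defaults 105.38 for 2009 prices, 109.02 for the 2011 index year).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(wtp_threshold = 18000,
                            wtp_grid = seq(0, 100000, by = 500),
                            n_reps_costs = 5000L,
                            n_reps_ceac = 1000L,
                            seed = 1L,
                            scenario = c("primary", "sensitivity"),
                            auc_method = c("trapezoid", "rectangle"),
                            cpi_from = 105.38,
                            cpi_to = 109.02) {
  scenario <- match.arg(scenario)
  auc_method <- match.arg(auc_method)
  if (!is.finite(wtp_threshold) || wtp_threshold < 0)
    stop("wtp_threshold must be >= 0", call. = FALSE)
  if (n_reps_costs < 1L || n_reps_ceac < 1L)
    stop("bootstrap replicate counts must be >= 1", call. = FALSE)
  if (length(wtp_grid) < 1L || any(wtp_grid < 0))
    stop("wtp_grid must be non-empty and non-negative", call. = FALSE)
  if (is.null(seed) || !is.finite(seed))
    stop("seed must be set", call. = FALSE)
  structure(list(wtp_threshold = wtp_threshold, wtp_grid = wtp_grid,
                 n_reps_costs = as.integer(n_reps_costs),
                 n_reps_ceac = as.integer(n_reps_ceac),
                 seed = as.integer(seed), scenario = scenario,
                 auc_method = auc_method,
                 cpi_from = cpi_from, cpi_to = cpi_to),
            class = "analysis_config")
}

# Named deterministic substreams derived from one root seed, kept within
# 32-bit integer range.
derive_seed <- function(seed, stream = c("simulation", "missingness",
                                         "cost-bootstrap", "ceac-bootstrap")) {
  stream <- match.arg(stream)
  offset <- c(simulation = 101L, missingness = 202L,
              `cost-bootstrap` = 303L, `ceac-bootstrap` = 404L)[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
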