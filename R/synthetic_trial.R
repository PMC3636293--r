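# Synthetic three-arm trial generator. One row per participant per wave,
# long format, matching the canonical participant CSV schema.

#' Generate a synthetic three-arm smoking-cessation trial
#'
#' Draws a complete (no missingness) participant-level long-format dataset
#' with the statistical structure the downstream economic evaluation assumes:
#' right-skewed health-care costs (negative-binomial resource-use counts
#' valued at unit prices), EQ-5D-3L item levels from a correlated ordinal
#' model calibrated so the scored baseline utility matches
#' `config$utility_mean`, per-arm prolonged-abstinence probabilities, and
#' FTND addiction scores.
#'
#' Apply \code{\link{apply_missingness}} afterwards to emulate loss to
#' follow-up.
#'
#' @param config a \code{\link{trial_config}}.
#' @return data.frame with columns id, arm, age, sex, education, wave,
#'   wave_time, one count column per `cost_categories()`, the five
#'   `eq5d_items()` columns, smoking_status (1 = not abstinent,
#'   2 = abstinent) and ftnd (0-10).
#' @export
generate_trial <- function(config) {
  validate_trial_config(config)
  set.seed(derive_seed(config$seed, "simulation"))

  arms <- arm_levels()
  n_arm <- config$arm_sizes[arms]
  n <- sum(n_arm)
  n_wave <- length(config$wave_times)
  arm <- factor(rep(arms, n_arm), levels = arms)

  # demographics: middle-aged adult smokers recruited in general practice
  age <- round(pmax(18, rnorm(n, 48, 12)))
  sex <- factor(ifelse(runif(n) < 0.37, "male", "female"),
                levels = c("male", "female"))
  education <- factor(sample(c("high", "medium", "low"), n, replace = TRUE,
                             prob = c(0.23, 0.45, 0.32)),
                      levels = c("high", "medium", "low"))

  # smoking trajectories: prolonged quitters are abstinent from 6 months on
  p_quit <- config$abstinence_probs[as.character(arm)]
  quit <- runif(n) < p_quit
  # transient early quit attempts among eventual non-abstainers
  early <- runif(n) < ifelse(quit, 0.5, 0.12)
  mid_lapse <- runif(n) < 0.03

  ftnd0 <- pmin(10, pmax(0, round(rnorm(n, 5.4, 2.15))))

  prices <- indexed_unit_prices(default_unit_prices())
  mu_count <- sweep(config$cost_means[, arms, drop = FALSE], 1,
                    prices[cost_categories()], "/")
  size <- if (config$cost_dispersion > 0) 1 / config$cost_dispersion else Inf

  # EQ-5D item generator: one-factor ordinal probit, severity multiplier
  # calibrated so the scored mean utility matches utility_mean
  eq <- eq5d_generator_params(config$utility_mean, config$utility_sd)
  z <- rnorm(n)  # person-level latent severity factor

  rows <- vector("list", n_wave)
  for (w in seq_len(n_wave)) {
    counts <- sapply(cost_categories(), function(cat) {
      mu <- mu_count[cat, as.character(arm)]
      if (is.finite(size)) rnbinom(n, size = size, mu = mu)
      else stats::rpois(n, mu)
    })
    items <- draw_eq5d_items(z, eq)
    abstinent <- switch(as.character(w),
      "1" = rep(FALSE, n),
      "2" = early,
      as.logical(quit | (w == 3 & mid_lapse)))
    status <- ifelse(abstinent, 2L, 1L)
    ftnd <- pmin(10, pmax(0, round(ftnd0 + (w > 1) * rnorm(n, 0, 1) -
                                     2 * abstinent)))
    rows[[w]] <- data.frame(id = seq_len(n), arm = arm, age = age, sex = sex,
                            education = education, wave = w,
                            wave_time = config$wave_times[w],
                            counts, items,
                            smoking_status = status, ftnd = ftnd,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$wave), ]
  rownames(out) <- NULL
  out
}

# Baseline per-dimension probabilities of levels 2 and 3 (mobility,
# self-care, usual activities, pain/discomfort, anxiety/depression) for a
# middle-aged smoking population; scaled jointly by a severity multiplier
# during calibration.
eq5d_base_marginals <- function() {
  list(p2 = c(0.15, 0.05, 0.18, 0.38, 0.28),
       p3 = c(0.02, 0.01, 0.02, 0.04, 0.03))
}

# Calibrate the severity multiplier k so that E[utility] under the one-factor
# probit model equals the target mean. The expectation is computed by 1-D
# Gauss-type quadrature over the person factor z (dimensions are independent
# given z), so calibration is deterministic and seed-free.
eq5d_generator_params <- function(utility_mean, utility_sd) {
  loading <- min(0.95, max(0.2, 0.6 * utility_sd / 0.2))
  base <- eq5d_base_marginals()
  zg <- seq(-5, 5, length.out = 201)
  wg <- stats::dnorm(zg); wg <- wg / sum(wg)
  co <- dutch_tariff_coefficients()

  mean_utility_for <- function(k) {
    q2 <- pmin(0.97, k * (base$p2 + base$p3))  # P(level >= 2)
    q3 <- pmin(0.60, k * base$p3)              # P(level == 3)
    t2 <- qnorm(1 - q2); t3 <- qnorm(1 - q3)
    s <- sqrt(1 - loading^2)
    dec <- numeric(length(zg))
    p_all1 <- rep(1, length(zg)); p_no3 <- rep(1, length(zg))
    for (d in 1:5) {
      pge2 <- 1 - pnorm((t2[d] - loading * zg) / s)
      p3d <- 1 - pnorm((t3[d] - loading * zg) / s)
      p2d <- pge2 - p3d
      dec <- dec + p2d * co$level2[d] + p3d * co$level3[d]
      p_all1 <- p_all1 * (1 - pge2)
      p_no3 <- p_no3 * (1 - p3d)
    }
    dec <- dec + (1 - p_all1) * co$constant + (1 - p_no3) * co$n3
    sum(wg * (1 - dec))
  }

  k <- tryCatch(
    uniroot(function(k) mean_utility_for(k) - utility_mean,
            lower = 0.01, upper = 2.5, tol = 1e-6)$root,
    error = function(e) stop("cannot calibrate EQ-5D generator to utility_mean ",
                             utility_mean, call. = FALSE))
  q2 <- pmin(0.97, k * (base$p2 + base$p3))
  q3 <- pmin(0.60, k * base$p3)
  list(loading = loading, t2 = qnorm(1 - q2), t3 = qnorm(1 - q3))
}

# Draw one wave of EQ-5D item levels given person factors z.
draw_eq5d_items <- function(z, params) {
  n <- length(z)
  s <- sqrt(1 - params$loading^2)
  items <- sapply(1:5, function(d) {
    y <- params$loading * z + s * rnorm(n)
    1L + (y > params$t2[d]) + (y > params$t3[d])
  })
  colnames(items) <- eq5d_items()
  items
}

#' Apply monotone, age-dependent loss to follow-up
#'
#' Each participant drops out with probability following a logistic model in
#' age; the intercept is calibrated by root search so the marginal dropout
#' probability equals `config$dropout_rate`. A dropout's first missing wave is
#' drawn uniformly among follow-up waves and all measured fields from that
#' wave on are set missing (monotone missingness). Baseline is never missing.
#'
#' @param trial data.frame from \code{\link{generate_trial}}.
#' @param config the \code{\link{trial_config}} used to generate it.
#' @return The trial with missing entries (NA) introduced.
#' @export
apply_missingness <- function(trial, config) {
  validate_trial_config(config)
  if (config$dropout_rate == 0) return(trial)
  set.seed(derive_seed(config$seed, "missingness"))

  base <- trial[trial$wave == 1L, c("id", "age")]
  beta <- config$dropout_age_coefficient
  target <- config$dropout_rate
  # calibrate intercept: mean over participants of plogis(a + beta*age) = target
  a <- uniroot(function(a) mean(plogis(a + beta * base$age)) - target,
               lower = -50, upper = 50, tol = 1e-9)$root
  p_drop <- plogis(a + beta * base$age)
  drops <- runif(nrow(base)) < p_drop
  first_missing <- ifelse(drops,
                          sample(2:max(trial$wave), nrow(base), replace = TRUE),
                          Inf)
  names(first_missing) <- as.character(base$id)

  measured <- c(cost_categories(), eq5d_items(), "smoking_status", "ftnd")
  gone <- trial$wave >= first_missing[as.character(trial$id)]
  trial[gone, measured] <- NA
  trial
}

#' Write / read the canonical participant CSV
#'
#' Long format, one row per participant per wave, fixed column order.
#' @param trial participant data.frame.
#' @param path file path.
#' @return `read_trial_csv` returns the participant data.frame with arm,
#'   sex and education restored as factors.
#' @export
write_trial_csv <- function(trial, path) {
  write.csv(trial, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_trial(df)
  df$arm <- factor(df$arm, levels = arm_levels())
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("male", "female"))
  if ("education" %in% names(df))
    df$education <- factor(df$education, levels = c("high", "medium", "low"))
  df
}

#' Validate the participant table schema
#'
#' Checks column presence, arm labels, EQ-5D levels, smoking-status coding,
#' FTND range and count non-negativity; errors name the offending column and
#' rows.
#' @param trial candidate participant data.frame.
#' @return The table, invisibly, if valid.
#' @export
validate_trial <- function(trial) {
  need <- c("id", "arm", "wave", "wave_time", cost_categories(), eq5d_items(),
            "smoking_status", "ftnd")
  miss <- setdiff(need, names(trial))
  if (length(miss))
    stop("participant table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_arm <- !trial$arm %in% arm_levels()
  if (any(bad_arm))
    stop("column 'arm': unknown labels in rows ",
         paste(utils::head(which(bad_arm), 5), collapse = ", "), call. = FALSE)
  for (col in eq5d_items()) {
    v <- trial[[col]]
    bad <- !is.na(v) & !v %in% 1:3
    if (any(bad))
      stop("column '", col, "': EQ-5D levels must be 1, 2 or 3 (rows ",
           paste(utils::head(which(bad), 5), collapse = ", "), ")", call. = FALSE)
  }
  v <- trial$smoking_status
  bad <- !is.na(v) & !v %in% 1:2
  if (any(bad))
    stop("column 'smoking_status': must be 1 (not abstinent) or 2 (abstinent), rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  bad <- !is.na(trial$ftnd) & (trial$ftnd < 0 | trial$ftnd > 10)
  if (any(bad))
    stop("column 'ftnd': must be within 0-10, rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  for (col in cost_categories()) {
    v <- trial[[col]]
    bad <- !is.na(v) & v < 0
    if (any(bad))
      stop("column '", col, "': counts must be non-negative, rows ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(trial)
}
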