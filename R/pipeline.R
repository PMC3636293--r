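# End-to-end pipeline: read -> validate -> impute -> value -> score ->
# evaluate -> write. Artifacts are plain CSV with fixed column order;
# identical config + seed yields identical files.

#' Read an analysis configuration from YAML or JSON
#'
#' Recognized keys mirror \code{\link{analysis_config}} arguments; unknown
#' keys are rejected. Paths (`data`, `prices`, `value_set`, `output_dir`) are
#' returned alongside the config.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with elements `config` (\code{\link{analysis_config}}) and
#'   `paths`.
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  path_keys <- c("data", "prices", "value_set", "output_dir")
  cfg_keys <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), c(path_keys, cfg_keys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg_args <- raw[intersect(names(raw), cfg_keys)]
  if (!is.null(cfg_args$wtp_grid)) cfg_args$wtp_grid <- unlist(cfg_args$wtp_grid)
  list(config = do.call(analysis_config, cfg_args),
       paths = raw[intersect(names(raw), path_keys)])
}

#' Run the full economic-evaluation pipeline
#'
#' Reads the participant and unit-price CSVs, validates the schemas, applies
#' the intention-to-treat imputation rules, runs \code{\link{evaluate}}, and
#' writes the artifact set to the output directory: `arm_summaries.csv`,
#' `incrementals.csv`, `ceac.csv`, `cuac.csv`, `probabilities_at_wtp.csv`,
#' `cost_cis.csv`, `imputation_log.csv` (plus `*_sensitivity.csv` analogues
#' when the primary scenario is run). Seed, replicate counts, scenario and
#' imputation counts are logged via `message()`.
#'
#' @param data_path participant CSV (long format).
#' @param output_dir directory for artifacts (created if absent).
#' @param prices_path unit-price CSV; `NULL` for the packaged defaults.
#' @param value_set_path value-set CSV; `NULL` for the Dutch tariff.
#' @param config an \code{\link{analysis_config}}.
#' @return The `cea_results` bundle, invisibly.
#' @export
run_pipeline <- function(data_path, output_dir,
                         prices_path = NULL, value_set_path = NULL,
                         config = analysis_config()) {
  trial <- read_trial_csv(data_path)
  prices <- if (is.null(prices_path)) default_unit_prices()
  else read_unit_prices(prices_path)
  value_set <- if (is.null(value_set_path)) dutch_tariff_3l()
  else read_value_set(value_set_path)

  imp <- impute_trial(trial)
  message("seed=", config$seed, " scenario=", config$scenario,
          " reps_costs=", config$n_reps_costs,
          " reps_ceac=", config$n_reps_ceac,
          " imputed_cells=", nrow(imp$log),
          " cost_unavailable=", sum(!imp$availability$cost_available),
          " qaly_unavailable=", sum(!imp$availability$qaly_available))

  usable <- imp$availability$id[imp$availability$cost_available &
                                  imp$availability$qaly_available]
  trial_use <- imp$trial[imp$trial$id %in% usable, ]
  res <- evaluate(trial_use, prices, config, value_set)

  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_results(res, output_dir)
  wr <- function(df, f) write.csv(df, file.path(output_dir, f),
                                  row.names = FALSE, quote = FALSE)
  wr(imp$log, "imputation_log.csv")
  invisible(res)
}

# Write one results bundle (rounding only at write time: euros to 2 dp,
# probabilities/QALYs to 4 dp).
write_results <- function(res, output_dir, suffix = "") {
  wr <- function(df, name) {
    write.csv(df, file.path(output_dir, paste0(name, suffix, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  summ <- res$arm_summaries
  summ$mean_healthcare_cost <- round(summ$mean_healthcare_cost, 2)
  summ$mean_cost <- round(summ$mean_cost, 2)
  summ$p_abstinent <- round(summ$p_abstinent, 4)
  summ$mean_qaly <- round(summ$mean_qaly, 4)
  wr(summ, "arm_summaries")

  incr <- res$incrementals
  incr$delta_cost <- round(incr$delta_cost, 2)
  incr$delta_effect <- round(incr$delta_effect, 4)
  incr$ratio <- round(incr$ratio, 2)
  wr(incr, "incrementals")

  cis <- res$cost_cis
  cis[c("mean_diff", "lower", "upper")] <-
    round(cis[c("mean_diff", "lower", "upper")], 2)
  wr(cis, "cost_cis")

  rnd <- function(cv) { cv[-1] <- round(cv[-1], 4); cv }
  wr(rnd(as.data.frame(res$ceac)), "ceac")
  wr(rnd(as.data.frame(res$cuac)), "cuac")
  pw <- res$probabilities_at_wtp
  pw[setdiff(names(pw), c("outcome", "wtp"))] <-
    round(pw[setdiff(names(pw), c("outcome", "wtp"))], 4)
  wr(pw, "probabilities_at_wtp")

  if (!is.null(res$sensitivity))
    write_results(res$sensitivity, output_dir, suffix = "_sensitivity")
  invisible(NULL)
}

#' Simulate a synthetic trial to CSV
#'
#' Generates a trial with \code{\link{generate_trial}}, applies loss to
#' follow-up with \code{\link{apply_missingness}}, and writes the canonical
#' participant CSV.
#'
#' @param path output CSV path.
#' @param config a \code{\link{trial_config}}.
#' @return The path, invisibly.
#' @export
simulate_trial_csv <- function(path, config = trial_config()) {
  trial <- apply_missingness(generate_trial(config), config)
  write_trial_csv(trial, path)
}
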