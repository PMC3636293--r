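# Valuation of measured resource use in euros (societal perspective).
# Unit prices follow the Dutch costing manual convention: 2009 standard
# prices indexed to the 2011 price year via the consumer price index.

#' Index a price between price years
#'
#' Multiplicative consumer-price-index adjustment:
#' `price * cpi_to / cpi_from`.
#'
#' @param price euro amount in the source price year.
#' @param cpi_from,cpi_to consumer price indices of the source and target
#'   years (defaults: 105.38 for 2009, 109.02 for 2011).
#' @return Indexed euro amount.
#' @export
index_price <- function(price, cpi_from = 105.38, cpi_to = 109.02) {
  if (any(!is.finite(cpi_from)) || any(cpi_from <= 0))
    stop("cpi_from must be positive", call. = FALSE)
  if (any(price < 0, na.rm = TRUE)) stop("price must be non-negative", call. = FALSE)
  price * cpi_to / cpi_from
}

#' Cost of a medication course from defined daily doses
#'
#' Pharmacy price build-up used for prescribed smoking-cessation medication:
#' the DDD price over the days of use, less the statutory clawback discount,
#' plus VAT, plus a per-prescription dispensing charge when any medication
#' was used.
#'
#' @param ddd_price euro per defined daily dose.
#' @param days days of use (>= 0).
#' @param vat_rate value-added-tax rate (default 6%).
#' @param prescription_charge euro dispensing fee per prescription
#'   (default 6.00).
#' @param clawback_rate statutory pharmacist discount rate (default 6.82%).
#' @return Euro cost of the course.
#' @export
medication_cost <- function(ddd_price, days, vat_rate = 0.06,
                            prescription_charge = 6.00,
                            clawback_rate = 0.0682) {
  if (any(c(ddd_price, days, prescription_charge) < 0))
    stop("ddd_price, days and prescription_charge must be non-negative",
         call. = FALSE)
  if (any(c(vat_rate, clawback_rate) < 0) || any(c(vat_rate, clawback_rate) >= 1))
    stop("vat_rate and clawback_rate must be in [0, 1)", call. = FALSE)
  ddd_price * days * (1 - clawback_rate) * (1 + vat_rate) +
    prescription_charge * (days > 0)
}

#' Default unit-price table
#'
#' Standard 2009 prices per care contact (euro), with the medication category
#' priced per course via \code{\link{medication_cost}} on a representative
#' 30-day nicotine-replacement DDD price. Sources follow the costing-manual
#' hierarchy: standardized price where available, else real cost or tariff,
#' and the lowest price under uncertainty.
#'
#' @return data.frame with columns category, unit_price, price_year, source.
#' @export
default_unit_prices <- function() {
  data.frame(
    category = cost_categories(),
    unit_price = c(28.00, 72.00, 457.00, 50.00, 94.00,
                   round(medication_cost(1.40, 30), 2), 20.00, 30.00),
    price_year = 2009L,
    source = c("standard", "standard", "standard", "lowest", "standard",
               "real_cost", "tariff", "lowest"),
    stringsAsFactors = FALSE)
}

#' Read and validate a unit-price CSV
#'
#' Expected columns: category, unit_price, price_year, source.
#' @param path CSV path.
#' @return Validated unit-price data.frame.
#' @export
read_unit_prices <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "unit_price", "price_year", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("unit-price table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$unit_price)) || any(df$unit_price < 0))
    stop("unit prices must be non-negative", call. = FALSE)
  if (any(is.na(df$price_year)))
    stop("price_year must be present for every entry", call. = FALSE)
  df
}

# Named vector of per-category prices indexed to the target price year.
indexed_unit_prices <- function(prices, cpi_from = 105.38, cpi_to = 109.02) {
  setNames(index_price(prices$unit_price, cpi_from, cpi_to), prices$category)
}

#' Annualize recall-window costs
#'
#' Each follow-up wave's 3-month recall cost is scaled to cover the gap since
#' the previous wave (`gap / recall_years`); the baseline recall window is
#' pre-randomization and excluded. The scaled follow-up costs are summed,
#' giving a euro-per-year amount over the follow-up horizon without double
#' counting.
#'
#' @param wave_costs euro per recall window, one per wave (baseline first).
#' @param wave_times wave times in years, strictly increasing from 0.
#' @param recall_years recall window length in years (default 0.25).
#' @return Annual euro amount.
#' @export
annualize_costs <- function(wave_costs, wave_times = c(0, 0.115, 0.5, 1),
                            recall_years = 0.25) {
  if (length(wave_costs) != length(wave_times))
    stop("wave_costs and wave_times must have equal length", call. = FALSE)
  if (wave_times[1] != 0 || any(diff(wave_times) <= 0))
    stop("wave_times must be strictly increasing and start at 0", call. = FALSE)
  if (recall_years <= 0 || recall_years > 1)
    stop("recall_years must be in (0, 1]", call. = FALSE)
  gaps <- diff(wave_times)
  sum(wave_costs[-1] * gaps / recall_years)
}

#' Value one participant's resource use
#'
#' Per-category annual euro amounts: counts are valued at indexed unit prices
#' wave by wave, then annualized with \code{\link{annualize_costs}}.
#'
#' @param record one participant's rows of the participant table (all waves),
#'   complete (imputed) counts.
#' @param prices unit-price data.frame (see \code{\link{default_unit_prices}}).
#' @param cpi_from,cpi_to price-index pair for indexing to the analysis year.
#' @param recall_years recall window length in years.
#' @return Named list: per-category annual euros (`categories`), their sum
#'   (`overall`), and the participant `id`.
#' @export
value_resource_use <- function(record, prices, cpi_from = 105.38,
                               cpi_to = 109.02, recall_years = 0.25) {
  used <- cost_categories()[colSums(record[cost_categories()], na.rm = TRUE) > 0 |
                              colSums(!is.na(record[cost_categories()])) > 0]
  unpriced <- setdiff(used, prices$category)
  if (length(unpriced))
    stop("no unit price for category: ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  p <- indexed_unit_prices(prices, cpi_from, cpi_to)
  record <- record[order(record$wave), ]
  per_cat <- vapply(cost_categories(), function(cat) {
    annualize_costs(record[[cat]] * p[[cat]], record$wave_time, recall_years)
  }, numeric(1))
  list(id = record$id[1], categories = per_cat, overall = sum(per_cat))
}

#' Intervention (programme) cost per participant
#'
#' Fixed per-participant delivery cost of each strategy. The primary scenario
#' counts programme delivery only (euro 57.70 for tailoring plus counselling,
#' 7.70 for tailoring only, 0 for usual care); the sensitivity scenario adds
#' monetised patient time and travel (141.89 / 82.24 / 0).
#'
#' @param arm arm label(s) among `arm_levels()`.
#' @param scenario `"primary"` or `"sensitivity"`.
#' @return Euro cost per participant (vectorized over `arm`).
#' @export
intervention_cost <- function(arm, scenario = c("primary", "sensitivity")) {
  scenario <- match.arg(scenario)
  tab <- switch(scenario,
                primary     = c(MTC = 57.70, MT = 7.70, UC = 0),
                sensitivity = c(MTC = 141.89, MT = 82.24, UC = 0))
  arm <- as.character(arm)
  bad <- !arm %in% names(tab)
  if (any(bad)) stop("unknown arm: ", paste(unique(arm[bad]), collapse = ", "),
                     call. = FALSE)
  unname(tab[arm])
}

#' Annual cost profiles for all participants
#'
#' Applies \code{\link{value_resource_use}} to every participant and adds the
#' per-arm intervention cost under the given scenario.
#'
#' @param trial complete (imputed) participant table.
#' @param prices unit-price data.frame.
#' @param scenario cost scenario passed to \code{\link{intervention_cost}}.
#' @param cpi_from,cpi_to price-index pair.
#' @param recall_years recall window length in years.
#' @return data.frame: id, arm, one annual euro column per category,
#'   healthcare_cost (category sum), intervention_cost, total_cost.
#' @export
value_costs <- function(trial, prices, scenario = "primary",
                        cpi_from = 105.38, cpi_to = 109.02,
                        recall_years = 0.25) {
  used <- cost_categories()[colSums(!is.na(trial[cost_categories()])) > 0]
  unpriced <- setdiff(used, prices$category)
  if (length(unpriced))
    stop("no unit price for category: ", paste(unpriced, collapse = ", "),
         call. = FALSE)
  p <- indexed_unit_prices(prices, cpi_from, cpi_to)

  trial <- trial[order(trial$id, trial$wave), ]
  # annualization weight per row: (gap since previous wave) / recall length,
  # zero for the pre-randomization baseline window
  gap <- stats::ave(trial$wave_time, trial$id,
                    FUN = function(t) c(0, diff(t)))
  w <- gap / recall_years

  ids <- unique(trial$id)
  cat_mat <- vapply(cost_categories(), function(cat) {
    rowsum(trial[[cat]] * p[[cat]] * w, trial$id, reorder = FALSE)[, 1]
  }, numeric(length(ids)))
  out <- data.frame(id = ids, arm = trial$arm[match(ids, trial$id)],
                    cat_mat, row.names = NULL)
  out$healthcare_cost <- rowSums(cat_mat)
  out$intervention_cost <- intervention_cost(out$arm, scenario)
  out$total_cost <- out$healthcare_cost + out$intervention_cost
  out
}
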