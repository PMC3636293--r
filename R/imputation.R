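# Intention-to-treat single-imputation rules for the four-wave series:
# interior single gaps take the mean of the two neighbouring waves; remaining
# gaps use last observation carried forward, leading gaps next observation
# carried backward; missing abstinence is treated as still smoking.

#' Impute one participant's wave series
#'
#' Rules, in order: leading missing values take the next observed value
#' (NOCB); an interior missing value whose immediate neighbours are both
#' observed takes their mean; any remaining missing value carries the last
#' observation forward (LOCF). For `kind = "eq5d_item"` the result is rounded
#' to the nearest level in 1..3, with halves rounding up (toward the more
#' severe level).
#'
#' @param series numeric vector over the waves, NA = missing.
#' @param kind `"continuous"` (costs, FTND, consumption) or `"eq5d_item"`.
#' @return The imputed series with attribute `"methods"` (character, per
#'   wave: `"observed"`, `"neighbor_mean"`, `"locf"` or `"nocb"`). An
#'   all-missing series is returned unchanged with attribute
#'   `"imputable" = FALSE`: the record counts as unavailable for analyses of
#'   that quantity.
#' @export
impute_series <- function(series, kind = c("continuous", "eq5d_item")) {
  kind <- match.arg(kind)
  n <- length(series)
  methods <- ifelse(is.na(series), "", "observed")
  if (all(is.na(series))) {
    attr(series, "imputable") <- FALSE
    attr(series, "methods") <- methods
    return(series)
  }
  obs <- which(!is.na(series))
  out <- series

  # leading gap: next observation carried backward
  first <- obs[1]
  if (first > 1) {
    out[seq_len(first - 1)] <- series[first]
    methods[seq_len(first - 1)] <- "nocb"
  }
  # interior single gaps with both immediate neighbours observed
  for (i in seq_len(n)) {
    if (is.na(series[i]) && i > 1 && i < n &&
        !is.na(series[i - 1]) && !is.na(series[i + 1])) {
      out[i] <- (series[i - 1] + series[i + 1]) / 2
      methods[i] <- "neighbor_mean"
    }
  }
  # everything else: last observation carried forward
  for (i in seq_len(n)) {
    if (is.na(out[i])) {
      out[i] <- out[i - 1]
      methods[i] <- "locf"
    }
  }
  if (kind == "eq5d_item") {
    out <- pmin(3, pmax(1, floor(out + 0.5)))  # .5 rounds toward severe
  }
  attr(out, "imputable") <- TRUE
  attr(out, "methods") <- methods
  out
}

#' Impute smoking abstinence under the negative scenario
#'
#' Participants lost to follow-up are considered still smoking: every missing
#' status becomes 1 (not abstinent); observed values are unchanged. Always
#' imputable, so abstinence analyses retain all randomized participants
#' (intention to treat).
#'
#' @param status vector of per-wave smoking status (1 = not abstinent,
#'   2 = abstinent, NA = missing).
#' @return Status vector without missing values.
#' @export
impute_abstinence <- function(status) {
  status[is.na(status)] <- 1L
  status
}

#' Impute a full participant table
#'
#' Applies \code{\link{impute_series}} per participant to every cost-category
#' count, EQ-5D item and the FTND score, and
#' \code{\link{impute_abstinence}} to smoking status. Participants with an
#' all-missing series are flagged unavailable for the corresponding analysis
#' (costs / QALYs) but kept for abstinence.
#'
#' @param trial participant table (long format).
#' @return List with elements `trial` (imputed table), `log` (data.frame id,
#'   field, wave, method for every imputed cell) and `availability`
#'   (data.frame id, cost_available, qaly_available, ftnd_available).
#' @export
impute_trial <- function(trial) {
  trial <- trial[order(trial$id, trial$wave), ]
  ids <- unique(trial$id)
  cont_fields <- c(cost_categories(), "ftnd")
  measured <- c(cont_fields, eq5d_items(), "smoking_status")
  if (!anyNA(trial[measured])) {
    return(list(trial = trial,
                log = data.frame(id = integer(), field = character(),
                                 wave = integer(), method = character(),
                                 stringsAsFactors = FALSE),
                availability = data.frame(id = ids, cost_available = TRUE,
                                          qaly_available = TRUE,
                                          ftnd_available = TRUE)))
  }
  logs <- list()
  avail <- data.frame(id = ids, cost_available = TRUE,
                      qaly_available = TRUE, ftnd_available = TRUE)

  idx_by_id <- split(seq_len(nrow(trial)), factor(trial$id, levels = ids))
  for (j in seq_along(ids)) {
    idx <- idx_by_id[[j]]
    waves <- trial$wave[idx]
    for (field in c(cont_fields, eq5d_items())) {
      kind <- if (field %in% eq5d_items()) "eq5d_item" else "continuous"
      s <- impute_series(trial[[field]][idx], kind)
      if (isFALSE(attr(s, "imputable"))) {
        if (field %in% cost_categories()) avail$cost_available[j] <- FALSE
        if (field %in% eq5d_items()) avail$qaly_available[j] <- FALSE
        if (field == "ftnd") avail$ftnd_available[j] <- FALSE
        next
      }
      m <- attr(s, "methods")
      filled <- which(!m %in% c("observed", ""))
      if (length(filled))
        logs[[length(logs) + 1L]] <- data.frame(
          id = ids[j], field = field, wave = waves[filled],
          method = m[filled], stringsAsFactors = FALSE)
      trial[[field]][idx] <- as.numeric(s)
    }
    st <- trial$smoking_status[idx]
    was_na <- which(is.na(st))
    trial$smoking_status[idx] <- impute_abstinence(st)
    if (length(was_na))
      logs[[length(logs) + 1L]] <- data.frame(
        id = ids[j], field = "smoking_status", wave = waves[was_na],
        method = "negative_scenario", stringsAsFactors = FALSE)
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(id = integer(), field = character(), wave = integer(),
               method = character(), stringsAsFactors = FALSE)
  list(trial = trial, log = log_df, availability = avail)
}
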