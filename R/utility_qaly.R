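# EQ-5D-3L utility scoring and area-under-the-curve QALY accumulation.
# The default value set is the Dutch tariff (Lamers et al. 2006), an additive
# decrement model over the 243 health states, built here from its published
# coefficients and anchored at 11111 -> 1.0 (worst state 33333 -> -0.329).

dutch_tariff_coefficients <- function() {
  list(constant = 0.071,  # any departure from full health
       level2 = c(0.036, 0.082, 0.032, 0.086, 0.124),  # MO SC UA PD AD
       level3 = c(0.161, 0.152, 0.057, 0.329, 0.325),
       n3 = 0.234)        # any dimension at level 3
}

#' Dutch EQ-5D-3L tariff
#'
#' The full 243-state value set computed from the published Dutch time
#' trade-off coefficients: utility = 1 minus a constant for any departure
#' from full health, per-dimension level-2/level-3 decrements, and an extra
#' decrement when any dimension is at level 3.
#'
#' @return data.frame with columns `state` (five-digit string, levels of
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression) and `utility`.
#' @export
dutch_tariff_3l <- function() {
  co <- dutch_tariff_coefficients()
  grid <- expand.grid(ad = 1:3, pd = 1:3, ua = 1:3, sc = 1:3, mo = 1:3)
  lev <- as.matrix(grid[, c("mo", "sc", "ua", "pd", "ad")])
  dec <- co$constant * (rowSums(lev > 1) > 0) +
    (lev[, 1] == 2) * co$level2[1] + (lev[, 1] == 3) * co$level3[1] +
    (lev[, 2] == 2) * co$level2[2] + (lev[, 2] == 3) * co$level3[2] +
    (lev[, 3] == 2) * co$level2[3] + (lev[, 3] == 3) * co$level3[3] +
    (lev[, 4] == 2) * co$level2[4] + (lev[, 4] == 3) * co$level3[4] +
    (lev[, 5] == 2) * co$level2[5] + (lev[, 5] == 3) * co$level3[5] +
    co$n3 * (rowSums(lev == 3) > 0)
  vs <- data.frame(state = apply(lev, 1, paste, collapse = ""),
                   utility = 1 - dec, stringsAsFactors = FALSE)
  vs[order(vs$state), , drop = FALSE]
}

#' Read and validate a value-set CSV
#'
#' Expected columns: `state` (five digits, levels 1-3) and `utility`. The set
#' must cover all 243 states and anchor full health (11111) at 1.0.
#' @param path CSV path.
#' @return Validated value-set data.frame.
#' @export
read_value_set <- function(path) {
  vs <- read.csv(path, colClasses = c(state = "character"))
  validate_value_set(vs)
}

validate_value_set <- function(vs) {
  if (!all(c("state", "utility") %in% names(vs)))
    stop("value set needs columns 'state' and 'utility'", call. = FALSE)
  vs$state <- as.character(vs$state)
  all_states <- dutch_tariff_3l()$state
  miss <- setdiff(all_states, vs$state)
  if (length(miss))
    stop("value set must define all 243 EQ-5D-3L states; missing e.g. ",
         miss[1], call. = FALSE)
  if (abs(vs$utility[vs$state == "11111"] - 1) > 1e-12)
    stop("value set must anchor state 11111 at utility 1.0", call. = FALSE)
  if (any(vs$utility > 1))
    stop("utilities cannot exceed 1", call. = FALSE)
  vs
}

#' Score EQ-5D-3L health states
#'
#' @param levels a length-5 vector of item levels, an n x 5 matrix, or a
#'   character vector of five-digit states (e.g. `"21111"`).
#' @param value_set value-set data.frame (default the Dutch tariff).
#' @return Utility value(s).
#' @export
state_to_utility <- function(levels, value_set = dutch_tariff_3l()) {
  if (is.character(levels)) {
    states <- levels
    digs <- suppressWarnings(
      do.call(rbind, lapply(strsplit(states, ""), as.integer)))
    if (any(is.na(digs)) || ncol(digs) != 5)
      stop("states must be five digits with levels in 1-3", call. = FALSE)
    levels <- digs
  }
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1)
  if (ncol(levels) != 5)
    stop("EQ-5D-3L states have five dimensions", call. = FALSE)
  if (any(is.na(levels)) || any(!levels %in% 1:3))
    stop("EQ-5D-3L levels must be 1, 2 or 3", call. = FALSE)
  states <- apply(levels, 1, paste, collapse = "")
  u <- value_set$utility[match(states, value_set$state)]
  if (anyNA(u))
    stop("state not defined in value set: ",
         states[which(is.na(u))[1]], call. = FALSE)
  u
}

#' QALYs by area under the utility curve
#'
#' Integrates the utility profile over the follow-up horizon. The default is
#' the trapezoid rule (linear interpolation between measurements); the
#' rectangle rule (each utility held constant until the next measurement) is
#' available for sensitivity analyses.
#'
#' @param utilities utility per wave.
#' @param times wave times in years, strictly increasing.
#' @param method `"trapezoid"` or `"rectangle"`.
#' @return QALYs accumulated over the profile's span. A warning is issued
#'   when the span is not 1 year (the value is still the integral over the
#'   given span).
#' @export
qaly_auc <- function(utilities, times = c(0, 0.115, 0.5, 1),
                     method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  if (length(utilities) != length(times) || length(times) < 2)
    stop("utilities and times must have equal length >= 2", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (anyNA(utilities)) stop("utilities must be complete", call. = FALSE)
  span <- times[length(times)] - times[1]
  if (abs(span - 1) > 1e-9)
    warning("utility profile spans ", span,
            " years, not the 12-month horizon", call. = FALSE)
  dt <- diff(times)
  n <- length(utilities)
  switch(method,
         trapezoid = sum(dt * (utilities[-1] + utilities[-n]) / 2),
         rectangle = sum(dt * utilities[-n]))
}

#' Score utilities and QALYs for a participant table
#'
#' Adds a `utility` column (per row, from the EQ-5D items) and returns
#' per-participant QALYs over the follow-up.
#'
#' @param trial complete (imputed) participant table.
#' @param value_set value-set data.frame.
#' @param auc_method passed to \code{\link{qaly_auc}}.
#' @return data.frame: id, arm, qaly.
#' @export
compute_qalys <- function(trial, value_set = dutch_tariff_3l(),
                          auc_method = "trapezoid") {
  trial <- trial[order(trial$id, trial$wave), ]
  u <- state_to_utility(as.matrix(trial[eq5d_items()]), value_set)
  ids <- unique(trial$id)
  qalys <- vapply(split(seq_len(nrow(trial)),
                        factor(trial$id, levels = ids)), function(idx) {
    qaly_auc(u[idx], trial$wave_time[idx], auc_method)
  }, numeric(1))
  data.frame(id = ids, arm = trial$arm[match(ids, trial$id)],
             qaly = unname(qalys), row.names = NULL)
}
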