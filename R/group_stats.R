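# Baseline-comparability and effect-comparison statistics, computed from the
# definitional formulas (cross-checked against stats::chisq.test and
# stats::aov in the test suite).

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the row/column margins; `df = (rows - 1) * (cols - 1)`. No continuity
#' correction is applied.
#'
#' @param counts matrix of non-negative counts (arms x outcome levels).
#' @return List: `statistic`, `df`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin", call. = FALSE)
  expected <- outer(rs, cs) / n
  list(statistic = sum((counts - expected)^2 / expected),
       df = (nrow(counts) - 1) * (ncol(counts) - 1))
}

#' Chi-square from per-arm successes and sizes
#'
#' Convenience wrapper building the k x 2 table of (successes, failures).
#' @param successes,sizes integer vectors per arm.
#' @return As \code{\link{chi_square}}.
#' @export
chi_square_props <- function(successes, sizes) {
  if (any(successes > sizes)) stop("successes exceed arm sizes", call. = FALSE)
  chi_square(cbind(successes, sizes - successes))
}

#' One-way analysis-of-variance F statistic
#'
#' `F = MS_between / MS_within` from the standard between/within sums of
#' squares.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return List: `statistic` (NaN when both between- and within-group
#'   variation are zero), `df_between`, `df_within`.
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  k <- length(groups)
  n_g <- vapply(groups, length, 1L)
  n <- sum(n_g)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n_g * means) / n
  ss_between <- sum(n_g * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- n - k
  f <- (ss_between / df_b) / (ss_within / df_w)  # 0/0 -> NaN (degenerate)
  list(statistic = f, df_between = df_b, df_within = df_w)
}
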