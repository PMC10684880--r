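# HENI scoring: converts dietary-risk intakes per 100 kcal into minutes of
# healthy life via DALY-scale risk factors. Negative factors are
# beneficial; the -0.53 minutes-per-microDALY-scale conversion flips the
# sign so that beneficial intakes yield positive minutes.

#' Minutes conversion constant of the HENI model
#'
#' The published DALY-scale-to-minutes multiplier, -0.53, applied to the
#' factor-weighted intake sum.
#' @return -0.53
#' @export
heni_minutes_constant <- function() -0.53

.check_risk_table <- function(t) {
  need <- c("risk", "factor")
  if (!is.data.frame(t) || !all(need %in% names(t))) {
    stop_dietshift("KEY_MISMATCH", "factor table must have columns risk, factor")
  }
  if (nrow(t) != 15 || anyDuplicated(t$risk)) {
    stop_dietshift("KEY_MISMATCH", "factor table must have 15 unique risks, got %d", nrow(t))
  }
  t
}

#' HENI score of a dietary-risk intake vector
#'
#' Computes `-0.53 * sum_r factor_r * d_r` over the 15 dietary risks. `d`
#' must be expressed per 100 kcal in the intake units declared by the
#' factor table.
#'
#' @param d Named numeric vector: risk -> intake per 100 kcal. Names must
#'   match the factor table's risk set exactly.
#' @param t Factor table (default the packaged published table),
#'   data frame with columns `risk`, `factor`.
#' @return HENI in minutes of healthy life per 100 kcal.
#' @export
heni_score <- function(d, t = heni_factors()) {
  .check_risk_table(t)
  if (is.null(names(d)) || !setequal(names(d), t$risk)) {
    stop_dietshift("KEY_MISMATCH",
                   "intake vector risks do not match the factor table")
  }
  if (any(d < 0)) {
    stop_dietshift("KEY_MISMATCH", "risk intakes must be non-negative")
  }
  f <- stats::setNames(t$factor, t$risk)
  heni_minutes_constant() * sum(f[names(d)] * d)
}

#' Percent contribution of each risk to the HENI score
#'
#' Contribution of risk r is `|factor_r * d_r|` as a percentage of the sum
#' of absolute factor-weighted intakes; contributions sum to 100.
#'
#' @inheritParams heni_score
#' @return Named numeric vector of percentages summing to 100.
#' @export
risk_contributions <- function(d, t = heni_factors()) {
  .check_risk_table(t)
  if (is.null(names(d)) || !setequal(names(d), t$risk)) {
    stop_dietshift("KEY_MISMATCH",
                   "intake vector risks do not match the factor table")
  }
  f <- stats::setNames(t$factor, t$risk)
  comp <- abs(f[names(d)] * d)
  total <- sum(comp)
  if (total == 0) {
    stop_dietshift("ALL_ZERO", "all factor-weighted intakes are zero")
  }
  100 * comp / total
}
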