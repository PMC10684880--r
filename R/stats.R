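# Trade-off statistics layer: correlations, subgroup summaries, threshold
# counts, Kruskal-Wallis-style ranking and Pareto flagging over the
# per-scenario score table.

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around the standard product-moment correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop_dietshift("LENGTH_MISMATCH", "x and y lengths differ (%d vs %d)",
                   length(x), length(y))
  }
  if (length(x) < 3) {
    stop_dietshift("LENGTH_MISMATCH", "need at least 3 observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_dietshift("ZERO_VARIANCE", "input has zero variance")
  }
  stats::cor(x, y, method = "pearson")
}

.check_score_table <- function(t) {
  if (!is.data.frame(t) || !"scenario_id" %in% names(t)) {
    stop_dietshift("EMPTY_TABLE", "score table must have a scenario_id column")
  }
  if (anyDuplicated(t$scenario_id)) {
    stop_dietshift("EMPTY_TABLE", "duplicate scenario ids")
  }
  t
}

#' Mean and sample SD of a score column over a scenario subset
#'
#' Subsets are explicit id lists because prose subgroup definitions are
#' ambiguous; the sample (n-1) standard deviation is used.
#'
#' @param t Score table (data frame with `scenario_id` and score columns).
#' @param ids Character vector of scenario ids (must all exist in `t`).
#' @param column Score column name.
#' @return List with `mean`, `sd` (`NA` with a warning for singletons) and
#'   `n`.
#' @export
subset_stats <- function(t, ids, column) {
  .check_score_table(t)
  if (length(ids) == 0) stop_dietshift("EMPTY_SUBSET", "empty scenario subset")
  miss <- setdiff(ids, t$scenario_id)
  if (length(miss)) {
    stop_dietshift("EMPTY_SUBSET", "unknown scenario id(s): %s",
                   paste(miss, collapse = ", "))
  }
  v <- t[[column]][match(ids, t$scenario_id)]
  s <- if (length(v) < 2) {
    warn_dietshift("SINGLETON_SUBSET", "SD undefined for a singleton subset")
    NA_real_
  } else {
    stats::sd(v)
  }
  list(mean = mean(v), sd = s, n = length(v))
}

#' Count scenarios with a score strictly above a threshold
#'
#' @param t Score table.
#' @param column Score column name.
#' @param threshold Threshold; the inequality is strict (`value > threshold`).
#' @return Integer count.
#' @export
count_above <- function(t, column, threshold) {
  .check_score_table(t)
  sum(t[[column]] > threshold)
}

#' Kruskal-Wallis H statistic with tie correction
#'
#' Computed from explicit rank sums:
#' `H = (12 / (N (N + 1))) * sum_j n_j (Rbar_j - (N + 1) / 2)^2`, divided
#' by the tie correction `1 - sum(t^3 - t) / (N^3 - N)` over tie groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return The tie-corrected H statistic.
#' @export
kruskal_h <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  n_total <- length(values)
  r <- rank(values)
  groups <- as.factor(groups)
  h <- 12 / (n_total * (n_total + 1)) *
    sum(tapply(r, groups, function(ri) {
      length(ri) * (mean(ri) - (n_total + 1) / 2)^2
    }))
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n_total^3 - n_total)
  if (correction > 0) h <- h / correction
  h
}

#' Rank scenarios by a score column
#'
#' Rank 1 is best under the chosen direction; ties get the average rank.
#' When group labels are supplied, the Kruskal-Wallis H statistic (with
#' tie correction) and the per-group mean ranks are attached, exposing the
#' rank machinery behind the nonparametric ranking of scenarios.
#'
#' @param t Score table.
#' @param column Score column name.
#' @param direction `"desc"` (default; higher score is better, rank 1) or
#'   `"asc"` (lower is better, e.g. environmental impacts).
#' @param groups Optional vector of group labels aligned with `t`'s rows.
#' @return Data frame `scenario_id`, `value`, `rank`; if `groups` given,
#'   attributes `kruskal_h` and `mean_ranks`.
#' @export
rank_scenarios <- function(t, column, direction = c("desc", "asc"),
                           groups = NULL) {
  .check_score_table(t)
  direction <- match.arg(direction)
  if (nrow(t) < 2) stop_dietshift("EMPTY_TABLE", "need at least 2 scenarios to rank")
  v <- t[[column]]
  r <- if (direction == "desc") rank(-v) else rank(v)
  out <- data.frame(scenario_id = t$scenario_id, value = v, rank = r,
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(t))
    attr(out, "kruskal_h") <- kruskal_h(v, groups)
    attr(out, "mean_ranks") <- tapply(r, as.factor(groups), mean)
  }
  out
}

#' Dual-scale trade-off series with Pareto flags
#'
#' Pairs each scenario's nutrition score with one environmental indicator
#' and flags scenarios not dominated by any other: a scenario is dominated
#' if some other scenario has nutrition >= and impact <= with at least one
#' strict inequality.
#'
#' @param t Score table containing both columns.
#' @param nutrition_column Column holding the nutrition score (higher is
#'   better).
#' @param indicator_column Column holding the impact value (lower is
#'   better).
#' @return Data frame `scenario_id`, `nutrition`, `impact`, `pareto`
#'   (logical non-dominated flag).
#' @export
tradeoff_table <- function(t, nutrition_column, indicator_column) {
  .check_score_table(t)
  if (!indicator_column %in% names(t) || anyNA(t[[indicator_column]])) {
    stop_dietshift("MISSING_IMPACTS", "impact column '%s' missing or incomplete",
                   indicator_column)
  }
  score <- t[[nutrition_column]]
  impact <- t[[indicator_column]]
  n <- nrow(t)
  dominated <- vapply(seq_len(n), function(i) {
    any(score >= score[i] & impact <= impact[i] &
          (score > score[i] | impact < impact[i]))
  }, logical(1))
  data.frame(scenario_id = t$scenario_id, nutrition = score, impact = impact,
             pareto = !dominated, stringsAsFactors = FALSE)
}

#' Indicator-by-indicator correlation matrix across scenarios
#'
#' @param m Numeric matrix or data frame, scenarios in rows and indicators
#'   in columns (>= 3 rows). Zero-variance columns are flagged with a
#'   warning and yield `NA` correlations rather than an error.
#' @param alpha Significance level for the two-sided t-test flag
#'   (default 0.01).
#' @return List with `r` (symmetric correlation matrix, unit diagonal),
#'   `p` (two-sided p-values from the t transform of r) and `significant`
#'   (logical matrix, `p < alpha`).
#' @export
correlation_matrix <- function(m, alpha = 0.01) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 3) stop_dietshift("EMPTY_TABLE", "need at least 3 scenarios")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warn_dietshift("ZERO_VARIANCE", "zero-variance column(s): %s",
                   paste(colnames(m)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(m))
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  list(r = r, p = p, significant = p < alpha)
}
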