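# Environmental footprint: 18 life-cycle midpoint indicators per diet, from
# per-food mean impacts normalized by the reference amount customarily
# consumed (RACC) into per-gram factors.

#' The 18 midpoint impact indicators
#'
#' @return Character vector of the 18 indicator names, fixed strings used
#'   throughout the package.
#' @export
impact_indicators <- function() {
  c("global warming short term", "global warming long term", "water use",
    "ionizing radiation", "mineral resources", "freshwater ecotoxicity",
    "ozone layer depletion", "fine particulate matter formation",
    "freshwater acidification", "fossil energy use", "marine eutrophication",
    "land occupation", "freshwater eutrophication", "terrestrial acidification",
    "human toxicity cancer", "human toxicity noncancer",
    "total ecosystem quality damage", "total human health damage")
}

.check_impact_table <- function(t) {
  need <- c("food_id", "racc_g", "indicator", "unit", "mean_per_racc")
  if (!is.data.frame(t) || !all(need %in% names(t))) {
    stop_dietshift("MISSING_FACTOR",
                   "impact table must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(t$racc_g <= 0)) stop_dietshift("ZERO_RACC", "racc_g must be positive")
  if (any(!is.finite(t$mean_per_racc) | t$mean_per_racc < 0)) {
    stop_dietshift("MISSING_FACTOR", "impact values must be finite and non-negative")
  }
  bad <- setdiff(unique(t$indicator), impact_indicators())
  if (length(bad)) {
    stop_dietshift("MISSING_FACTOR", "unknown indicator(s): %s",
                   paste(bad, collapse = ", "))
  }
  t
}

#' Per-gram impact factor
#'
#' Divides a food's mean impact per RACC serving by the RACC mass,
#' yielding the per-gram factor applied to ingredient masses.
#'
#' @param mean_impact Mean impact per RACC (any indicator unit).
#' @param racc_g RACC in grams, must be positive.
#' @return Impact per gram.
#' @export
per_gram_factor <- function(mean_impact, racc_g) {
  if (any(racc_g <= 0)) stop_dietshift("ZERO_RACC", "RACC must be positive")
  mean_impact / racc_g
}

#' Environmental impact vector of a diet (per diet-day)
#'
#' For each of the 18 indicators, sums `per_gram_factor * grams` over the
#' diet's ingredients. Groups may map to several foods via mass-weight
#' splits in `food_map`; the default is one representative food per group.
#'
#' @param c A validated `diet_composition`.
#' @param t Impact factor table: long data frame with columns `food_id`,
#'   `racc_g`, `indicator`, `unit`, `mean_per_racc`.
#' @param food_map Data frame `group`, `food_id` (optional `weight`).
#' @return Named numeric vector of class `impact_vector` over the 18
#'   indicators, with attributes `basis = "per-diet-day"` and `units`
#'   (named character vector carried verbatim from the table).
#' @export
diet_impacts <- function(c, t, food_map) {
  validate_composition(c)
  .check_impact_table(t)
  if (is.null(food_map$weight)) food_map$weight <- 1
  food_map$group <- canonical_group(food_map$group)
  groups <- names(c$shares)[c$shares > 0]
  missing <- setdiff(groups, unique(food_map$group))
  if (length(missing)) {
    stop_dietshift("MISSING_FACTOR", "no impact-table food mapped for: %s",
                   paste(missing, collapse = ", "))
  }
  ind <- impact_indicators()
  values <- stats::setNames(numeric(length(ind)), ind)
  units <- stats::setNames(rep(NA_character_, length(ind)), ind)
  for (g in groups) {
    grams <- grams_of(c, g)
    fm <- food_map[food_map$group == g, , drop = FALSE]
    w <- fm$weight / sum(fm$weight)
    for (j in seq_len(nrow(fm))) {
      rows <- t[t$food_id == fm$food_id[j], , drop = FALSE]
      if (!setequal(rows$indicator, ind)) {
        stop_dietshift("MISSING_FACTOR",
                       "food %s lacks factors for all 18 indicators", fm$food_id[j])
      }
      rows <- rows[match(ind, rows$indicator), ]
      values <- values + grams * w[j] * per_gram_factor(rows$mean_per_racc, rows$racc_g)
      units[ind] <- ifelse(is.na(units[ind]), rows$unit, units[ind])
    }
  }
  structure(values, basis = "per-diet-day", units = units,
            class = c("impact_vector", "numeric"))
}

#' Rebase an impact vector from per-day to per-100-kcal
#'
#' @param v An `impact_vector` on the per-diet-day basis.
#' @param total_kcal The diet's energy per day (kcal), must be positive.
#' @return The vector scaled by `100 / total_kcal`, basis flag updated.
#' @export
normalize_per_100kcal <- function(v, total_kcal) {
  stopifnot(inherits(v, "impact_vector"))
  if (total_kcal <= 0) stop_dietshift("ZERO_ENERGY", "total_kcal must be positive")
  structure(unclass(v) * 100 / total_kcal,
            basis = "per-100-kcal", units = attr(v, "units"),
            class = class(v))
}

#' Percent reduction of an impact relative to a baseline
#'
#' `(baseline - alternative) / baseline * 100`; positive values are
#' reductions.
#'
#' @param baseline Baseline quantity (nonzero).
#' @param alternative Alternative quantity.
#' @return Percent reduction.
#' @export
percent_change <- function(baseline, alternative) {
  if (any(baseline == 0)) stop_dietshift("ZERO_BASELINE", "baseline must be nonzero")
  (baseline - alternative) / baseline * 100
}
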