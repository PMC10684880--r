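# Scenario builder: the 24 diet scenarios interpolating between the
# current (S1), feasible (S5, midpoint) and optimal (S10) anchor diets by
# partial meat-to-legume substitution under consumption models M1-M3.

#' Bundle the three anchor diets
#'
#' @param current,feasible,optimal Validated `diet_composition` objects.
#'   If `feasible` is `NULL` it is constructed as the per-group arithmetic
#'   midpoint of `current` and `optimal`.
#' @param check_midpoint Warn if the supplied feasible anchor deviates from
#'   the midpoint by more than `tol_pp` percentage points in any group.
#' @param tol_pp Midpoint tolerance, percent-of-mass units (default 0.01).
#' @return List of class `anchor_set`.
#' @export
anchor_set <- function(current, optimal, feasible = NULL,
                       check_midpoint = TRUE, tol_pp = 0.01) {
  validate_composition(current)
  validate_composition(optimal)
  if (current$total_mass_g != optimal$total_mass_g) {
    stop_dietshift("MASS_IMBALANCE", "anchor total masses differ")
  }
  if (is.null(feasible)) {
    feasible <- diet_composition((current$shares + optimal$shares) / 2,
                                 total_mass_g = current$total_mass_g)
  }
  validate_composition(feasible)
  anchors <- structure(
    list(current = current, feasible = feasible, optimal = optimal),
    class = "anchor_set"
  )
  if (check_midpoint) {
    dev <- check_anchor_midpoint(anchors)
    if (any(dev$deviation_pp > tol_pp)) {
      warn_dietshift("MIDPOINT_DEVIATION",
        "feasible anchor deviates from the current/optimal midpoint by up to %.3f pp",
        max(dev$deviation_pp))
    }
  }
  anchors
}

#' Report feasible-anchor deviation from the current/optimal midpoint
#'
#' The feasible diet is defined as the midpoint diet between the current
#' and optimal diets; this reports the per-group absolute deviation of the
#' supplied feasible anchor from that midpoint, in percent-of-mass units.
#'
#' @param anchors An `anchor_set`.
#' @return Data frame with columns `group`, `feasible_pct`, `midpoint_pct`,
#'   `deviation_pp`.
#' @export
check_anchor_midpoint <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  mid <- (anchors$current$shares + anchors$optimal$shares) / 2
  data.frame(
    group = food_groups(),
    feasible_pct = 100 * unname(anchors$feasible$shares),
    midpoint_pct = 100 * unname(mid),
    deviation_pp = 100 * abs(unname(anchors$feasible$shares - mid)),
    stringsAsFactors = FALSE
  )
}

#' Step schedule for intermediate scenarios
#'
#' Two modes. `"linear"` interpolates targeted meat shares between the
#' segment anchors (S1->S5, S5->S10), credits the removed meat mass 1:1 to
#' legumes, pins all other groups to the feasible anchor and lets refined
#' grains absorb the residual so mass is conserved. `"override"` instead
#' takes the four targeted-group shares (legumes, processed, red, white)
#' for every intermediate scenario from an explicit table - by default the
#' packaged table of compositions printed in the source study, completed
#' with linear-mode values where no composition was printed.
#'
#' @param mode `"override"` (default) or `"linear"`.
#' @param overrides Data frame with columns `scenario_id`, `legumes`,
#'   `processed_meat`, `red_meat`, `white_meat` (percent of total mass).
#'   Required for every S2-S4/S6-S9 x model id in override mode; `NULL`
#'   defers to the packaged table at build time.
#' @return List of class `step_schedule`.
#' @export
step_schedule <- function(mode = c("override", "linear"), overrides = NULL) {
  mode <- match.arg(mode)
  if (!is.null(overrides)) {
    need <- c("scenario_id", "legumes", "processed_meat", "red_meat", "white_meat")
    if (!all(need %in% names(overrides))) {
      stop_dietshift("SCHEDULE_INCOMPLETE", "overrides must have columns: %s",
                     paste(need, collapse = ", "))
    }
    vals <- as.matrix(overrides[, need[-1]])
    if (any(vals < 0 | vals > 100)) {
      stop_dietshift("SCHEDULE_INCOMPLETE", "override shares must lie in [0, 100] percent")
    }
  }
  structure(list(mode = mode, overrides = overrides,
                 n_intermediate_low = 3, n_intermediate_high = 4),
            class = "step_schedule")
}

# Scenario ids for the full 24-scenario design.
scenario_ids <- function(models = c("M1", "M2", "M3")) {
  inter <- function(s) {
    if (length(models) == 0) return(character(0))
    paste0("S", s, rep(models, each = length(s)))
  }
  c("S1", inter(2:4), "S5", inter(6:9), "S10")
}

# Segment position of an intermediate scenario: S2-S4 sit at t = 1/4..3/4
# of current->feasible; S6-S9 at t = 1/5..4/5 of feasible->optimal.
.segment_of <- function(s_num) {
  if (s_num %in% 2:4) {
    list(from = "current", to = "feasible", t = (s_num - 1) / 4)
  } else {
    list(from = "feasible", to = "optimal", t = (s_num - 5) / 5)
  }
}

# Linear-mode targeted shares (percent) for scenario S<s_num> under `model`.
.linear_targets <- function(anchors, model, s_num) {
  seg <- .segment_of(s_num)
  a <- anchors[[seg$from]]$shares * 100
  b <- anchors[[seg$to]]$shares * 100
  meats <- c("processed meat", "red meat", "white meat")
  tgt <- a[meats]
  tgt[model$targeted_groups] <-
    a[model$targeted_groups] + seg$t * (b[model$targeted_groups] - a[model$targeted_groups])
  # non-targeted meats pinned to feasible for intermediates
  pin <- setdiff(meats, model$targeted_groups)
  tgt[pin] <- anchors$feasible$shares[pin] * 100
  removed <- sum(a[model$targeted_groups]) - sum(tgt[model$targeted_groups])
  legumes <- a["legumes"] + removed
  c(legumes = unname(legumes),
    processed_meat = unname(tgt["processed meat"]),
    red_meat = unname(tgt["red meat"]),
    white_meat = unname(tgt["white meat"]))
}

# Assemble a full composition for an intermediate scenario from its four
# targeted-group percentages: all other groups pinned to the feasible
# anchor, refined grains absorbing the residual mass.
.compose_intermediate <- function(anchors, targets_pct) {
  shares <- anchors$feasible$shares
  shares["legumes"] <- targets_pct[["legumes"]] / 100
  shares["processed meat"] <- targets_pct[["processed_meat"]] / 100
  shares["red meat"] <- targets_pct[["red_meat"]] / 100
  shares["white meat"] <- targets_pct[["white_meat"]] / 100
  residual <- 1 - sum(shares[setdiff(food_groups(), "refined grains")]) -
    anchors$feasible$shares[["refined grains"]]
  shares["refined grains"] <- anchors$feasible$shares[["refined grains"]] + residual
  if (shares[["refined grains"]] < -1e-9) {
    stop_dietshift("MASS_IMBALANCE",
      "targeted shares leave refined grains negative (%.3f%%)",
      100 * shares[["refined grains"]])
  }
  shares["refined grains"] <- max(shares[["refined grains"]], 0)
  diet_composition(shares, total_mass_g = anchors$current$total_mass_g)
}

#' Build the 24 diet scenarios
#'
#' Constructs S1 (current), S5 (feasible) and S10 (optimal) - shared across
#' consumption models - plus intermediates S2-S4 and S6-S9 for each model,
#' 24 scenarios in all. Every scenario conserves the anchors' total daily
#' mass.
#'
#' @param anchors An `anchor_set`.
#' @param models Character vector of model ids (default all of M1-M3).
#' @param schedule A `step_schedule` (default: override mode driven by the
#'   packaged printed-composition table).
#' @return List of class `scenario_set`: one element per scenario with
#'   fields `scenario_id`, `model`, `anchor_flag` and `composition`.
#' @export
build_scenarios <- function(anchors, models = c("M1", "M2", "M3"),
                            schedule = step_schedule("override")) {
  stopifnot(inherits(anchors, "anchor_set"), inherits(schedule, "step_schedule"))
  overrides <- schedule$overrides
  if (schedule$mode == "override" && is.null(overrides)) {
    overrides <- printed_schedule(anchors, models)$overrides
  }
  out <- list()
  add <- function(id, model, flag, comp) {
    out[[id]] <<- structure(
      list(scenario_id = id, model = model, anchor_flag = flag,
           composition = comp),
      class = "diet_scenario")
  }
  add("S1", "shared", "current", anchors$current)
  add("S5", "shared", "feasible", anchors$feasible)
  add("S10", "shared", "optimal", anchors$optimal)
  for (m in models) {
    cm <- consumption_model(m)
    for (s_num in c(2:4, 6:9)) {
      id <- paste0("S", s_num, m)
      if (schedule$mode == "override") {
        row <- overrides[overrides$scenario_id == id, , drop = FALSE]
        if (nrow(row) != 1) {
          stop_dietshift("SCHEDULE_INCOMPLETE",
                         "override schedule has no row for %s", id)
        }
        tgt <- c(legumes = row$legumes, processed_meat = row$processed_meat,
                 red_meat = row$red_meat, white_meat = row$white_meat)
      } else {
        tgt <- .linear_targets(anchors, cm, s_num)
      }
      add(id, m, "intermediate", .compose_intermediate(anchors, tgt))
    }
  }
  structure(out[scenario_ids(models)], class = "scenario_set")
}

#' Override schedule from the printed study compositions
#'
#' Builds a complete override table for S2-S4/S6-S9 x M1-M3: targeted-group
#' percentages exactly as printed in the source study's results for the ten
#' scenarios whose compositions are printed, and linear-mode values
#' (flagged `source = "linear-fill"`) for the rest, whose full compositions
#' were only published in a supplementary workbook.
#'
#' @param anchors An `anchor_set` (used for the linear fills).
#' @param models Model ids to cover.
#' @return A `step_schedule` in override mode; its `overrides` data frame
#'   carries a `source` column (`"printed"` or `"linear-fill"`).
#' @export
printed_schedule <- function(anchors, models = c("M1", "M2", "M3")) {
  printed <- printed_compositions()
  rows <- list()
  for (m in models) {
    cm <- consumption_model(m)
    for (s_num in c(2:4, 6:9)) {
      id <- paste0("S", s_num, m)
      hit <- printed[printed$scenario_id == id, , drop = FALSE]
      if (nrow(hit) == 1) {
        rows[[id]] <- data.frame(
          scenario_id = id, legumes = hit$legumes,
          processed_meat = hit$processed_meat, red_meat = hit$red_meat,
          white_meat = hit$white_meat, source = "printed",
          stringsAsFactors = FALSE)
      } else {
        tgt <- .linear_targets(anchors, cm, s_num)
        rows[[id]] <- data.frame(
          scenario_id = id, legumes = tgt[["legumes"]],
          processed_meat = tgt[["processed_meat"]], red_meat = tgt[["red_meat"]],
          white_meat = tgt[["white_meat"]], source = "linear-fill",
          stringsAsFactors = FALSE)
      }
    }
  }
  step_schedule("override", overrides = do.call(rbind, rows))
}

#' Long-format share table of a scenario set
#'
#' @param x A `scenario_set`.
#' @param ... Unused.
#' @return Data frame with `scenario_id`, `model`, `anchor_flag`, `group`,
#'   `percent_of_mass`, `grams`.
#' @export
as.data.frame.scenario_set <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(sc) {
    data.frame(
      scenario_id = sc$scenario_id, model = sc$model,
      anchor_flag = sc$anchor_flag, group = food_groups(),
      percent_of_mass = 100 * unname(sc$composition$shares),
      grams = unname(sc$composition$shares) * sc$composition$total_mass_g,
      stringsAsFactors = FALSE)
  }))
}
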