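# Delimited-text readers/writers for the pipeline's tables. All tables are
# plain CSV with the canonical column headers; compositions round-trip to
# full double precision.

#' Write / read diet compositions as CSV
#'
#' Long format: one row per scenario x group with columns `scenario_id`,
#' `group`, `share` (fraction) or `percent_of_mass`, plus `total_mass_g`.
#' The header flag is explicit: files written with `percent = TRUE` carry
#' `percent_of_mass` and are converted back to fractions on read.
#'
#' @param x Named list of `diet_composition` objects (names are scenario
#'   ids) or a single composition (written under id "diet").
#' @param path Output file.
#' @param percent Write shares as percent of mass (default `FALSE`:
#'   fractions, full precision).
#' @return `write_compositions` returns `path` invisibly;
#'   `read_compositions` a named list of `diet_composition` objects.
#' @export
write_compositions <- function(x, path, percent = FALSE) {
  if (inherits(x, "diet_composition")) x <- list(diet = x)
  rows <- do.call(rbind, lapply(names(x), function(id) {
    comp <- validate_composition(x[[id]])
    data.frame(scenario_id = id, group = food_groups(),
               value = unname(comp$shares) * if (percent) 100 else 1,
               total_mass_g = comp$total_mass_g, stringsAsFactors = FALSE)
  }))
  names(rows)[names(rows) == "value"] <-
    if (percent) "percent_of_mass" else "share"
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_compositions
#' @export
read_compositions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  percent <- "percent_of_mass" %in% names(df)
  valcol <- if (percent) "percent_of_mass" else "share"
  if (!all(c("scenario_id", "group", valcol, "total_mass_g") %in% names(df))) {
    stop_dietshift("UNKNOWN_GROUP", "composition file lacks required columns")
  }
  out <- lapply(split(df, df$scenario_id), function(d) {
    diet_composition(stats::setNames(as.numeric(d[[valcol]]), d$group),
                     total_mass_g = as.numeric(d$total_mass_g[1]),
                     percent = percent)
  })
  out[unique(df$scenario_id)]
}

#' Read an impact-factor table from CSV
#'
#' Expected columns: `food_id`, `racc_g`, `indicator`, `unit`,
#' `mean_per_racc` (long format, 18 indicators per food).
#'
#' @param path CSV file.
#' @return Validated impact-factor data frame.
#' @export
read_impact_factors <- function(path) {
  .check_impact_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a food-composition table from CSV
#'
#' @param path CSV file with `food_id`, `group`, `kcal_per_100g` and
#'   per-100-g nutrient columns.
#' @return Data frame with canonicalized group labels.
#' @export
read_food_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("food_id", "group", "kcal_per_100g") %in% names(df))) {
    stop_dietshift("MISSING_FOOD", "food table lacks required columns")
  }
  df$group <- canonical_group(df$group)
  df
}
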