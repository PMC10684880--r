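# Profile aggregation: fold a diet composition over a food-composition
# table into per-day nutrient totals, then rescale to the 100 kcal basis
# used by both scoring systems, and derive the 15-risk intake vector.

# nutrient columns expected (per 100 g) in a food-composition table
food_nutrient_columns <- function() {
  c("carbohydrate_g", "added_sugar_g", "fiber_g", "soluble_fiber_g",
    "protein_g", "plant_protein_g", "sat_fat_g", "unsat_fat_g", "pufa_g",
    "trans_fat_g", "cholesterol_mg", "ala_g", "epa_mg", "dha_mg",
    "sodium_mg", "potassium_mg", "calcium_mg", "iron_mg", "magnesium_mg",
    "zinc_mg", "phosphorus_mg", "selenium_ug", "copper_mg", "manganese_mg",
    "vitamin_a_ug", "vitamin_c_mg", "vitamin_d_ug", "vitamin_e_mg",
    "vitamin_k_ug", "thiamin_mg", "riboflavin_mg", "niacin_mg",
    "vitamin_b6_mg", "folate_ug", "vitamin_b12_ug", "choline_mg",
    "artificial_sweetener_mg")
}

# food-group -> ingredient attribute name (grams per 100 kcal in profiles)
.ingredient_attr <- c(
  "fruits" = "fruits", "vegetables" = "vegetables", "legumes" = "legumes",
  "whole grains" = "whole_grains", "nuts" = "nuts_seeds",
  "fish/seafood" = "seafood", "red meat" = "red_meats",
  "processed meat" = "processed_meats", "refined grains" = "refined_grains",
  "sugar-sweetened beverages" = "ssb"
)

# dietary risk -> (profile source key, multiplicative unit scale).
# Nutrient risks scale mg -> g where the factor table declares grams;
# food-group risks are grams of the group per 100 kcal.
.risk_sources <- list(
  "Calcium"                     = list(key = "calcium_mg", scale = 1e-3),
  "Polyunsaturated fatty acids" = list(key = "pufa_g", scale = 1),
  "Sodium"                      = list(key = "sodium_mg", scale = 1e-3),
  "Trans fats"                  = list(key = "trans_fat_g", scale = 1),
  "Whole grains"                = list(key = "group:whole grains", scale = 1),
  "Nuts and seeds"              = list(key = "group:nuts", scale = 1),
  "Legumes"                     = list(key = "group:legumes", scale = 1),
  "Vegetables"                  = list(key = "group:vegetables", scale = 1),
  "Fruits"                      = list(key = "group:fruits", scale = 1),
  "Seafood"                     = list(key = "group:fish/seafood", scale = 1),
  "Processed meats"             = list(key = "group:processed meat", scale = 1),
  "Red meats"                   = list(key = "group:red meat", scale = 1),
  "Milk"                        = list(key = "group:dairy", scale = 1),
  "Fiber"                       = list(key = "fiber_g", scale = 1),
  "Sugar-sweetened beverages"   = list(key = "group:sugar-sweetened beverages", scale = 1)
)

.resolve_food_map <- function(c, foods, food_map) {
  groups <- names(c$shares)[c$shares > 0]
  if (is.null(food_map)) {
    food_map <- data.frame(group = foods$group, food_id = foods$food_id,
                           weight = 1, stringsAsFactors = FALSE)
  }
  if (is.null(food_map$weight)) food_map$weight <- 1
  food_map$group <- canonical_group(food_map$group)
  missing <- setdiff(groups, unique(food_map$group))
  if (length(missing)) {
    stop_dietshift("MISSING_FOOD", "no representative food mapped for: %s",
                   paste(missing, collapse = ", "))
  }
  if (!all(food_map$food_id %in% foods$food_id)) {
    stop_dietshift("MISSING_FOOD", "food_map references foods absent from the table")
  }
  food_map
}

#' Aggregate a diet composition into per-100-kcal nutrient and risk profiles
#'
#' Per-day totals are computed ingredient-wise (grams of each group times
#' each representative food's per-gram density, mass-weighted when a group
#' maps to several foods) and rescaled to the 100 kcal basis used by the
#' Food Compass and HENI scoring systems. Derived ratio attributes and
#' per-100-kcal ingredient masses are added so the profile covers all 46
#' scoring attributes.
#'
#' @param c A validated `diet_composition`.
#' @param foods Food-composition table: data frame with `food_id`, `group`,
#'   `kcal_per_100g` and per-100-g nutrient columns
#'   (see [food_nutrient_columns()]; absent columns are treated as
#'   unmeasured and omitted from the profile).
#' @param food_map Optional data frame `group`, `food_id`, `weight` to map
#'   groups to (possibly several, mass-weight split) representative foods;
#'   default maps each group to all foods of that group with equal weight.
#' @return List with `profile` (class `nutrient_profile`: `amounts` per
#'   100 kcal, `total_kcal_per_day`, `basis_kcal`) and `risks` (named
#'   15-risk intake vector per 100 kcal, units as in the factor table).
#' @export
aggregate_profile <- function(c, foods, food_map = NULL) {
  validate_composition(c)
  stopifnot(is.data.frame(foods),
            all(c("food_id", "group", "kcal_per_100g") %in% names(foods)))
  foods$group <- canonical_group(foods$group)
  food_map <- .resolve_food_map(c, foods, food_map)
  nutr_cols <- intersect(food_nutrient_columns(), names(foods))

  groups <- names(c$shares)[c$shares > 0]
  kcal_day <- 0
  totals <- stats::setNames(numeric(length(nutr_cols)), nutr_cols)
  group_grams <- stats::setNames(numeric(length(food_groups())), food_groups())
  for (g in groups) {
    grams <- grams_of(c, g)
    group_grams[g] <- grams
    fm <- food_map[food_map$group == g, , drop = FALSE]
    w <- fm$weight / sum(fm$weight)
    rows <- foods[match(fm$food_id, foods$food_id), , drop = FALSE]
    kcal_day <- kcal_day + grams * sum(w * rows$kcal_per_100g) / 100
    for (n in nutr_cols) {
      totals[n] <- totals[n] + grams * sum(w * rows[[n]]) / 100
    }
  }
  if (kcal_day <= 0) {
    stop_dietshift("ZERO_ENERGY_DIET", "diet carries no energy")
  }

  per100 <- totals * 100 / kcal_day
  amounts <- as.list(per100)
  # derived ratio attributes (dimensionless, per 100 kcal basis cancels)
  gv <- function(n) if (n %in% names(per100)) per100[[n]] else NULL
  safe_ratio <- function(num, den) {
    if (is.null(num) || is.null(den) || den <= 0) 0 else num / den
  }
  amounts$fiber_carb_ratio <- safe_ratio(gv("fiber_g"), gv("carbohydrate_g"))
  amounts$potassium_sodium_ratio <- safe_ratio(gv("potassium_mg"), gv("sodium_mg"))
  amounts$added_sugar_carb_ratio <- safe_ratio(gv("added_sugar_g"), gv("carbohydrate_g"))
  amounts$unsat_sat_fat_ratio <- safe_ratio(gv("unsat_fat_g"), gv("sat_fat_g"))
  if (!is.null(amounts$sodium_mg)) amounts$additive_sodium_mg <- amounts$sodium_mg
  # ingredient attributes: grams of each group per 100 kcal
  group_per100 <- group_grams * 100 / kcal_day
  for (g in names(.ingredient_attr)) {
    amounts[[.ingredient_attr[[g]]]] <- unname(group_per100[g])
  }

  risks <- vapply(names(.risk_sources), function(r) {
    src <- .risk_sources[[r]]
    if (startsWith(src$key, "group:")) {
      unname(group_per100[sub("^group:", "", src$key)]) * src$scale
    } else if (src$key %in% names(per100)) {
      per100[[src$key]] * src$scale
    } else {
      0
    }
  }, numeric(1))

  profile <- structure(
    list(amounts = amounts, total_kcal_per_day = kcal_day, basis_kcal = 100),
    class = "nutrient_profile"
  )
  list(profile = profile, risks = risks)
}
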