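# Adapted Food Compass scoring: 46 attributes in 7 domains, each attribute
# scored on a monotone cut-point ladder against the diet's per-100-kcal
# profile, aggregated as mean-of-domains plus the food-ingredients sum and
# rescaled to 1-100.

.fcs_domains <- c(
  "nutrient ratios", "vitamins", "minerals", "food ingredients",
  "additives", "specific lipids", "protein & fiber"
)

# (name, domain, direction, reference scale per 100 kcal) for the 46
# retained attributes. Iodine, trans fats, medium-chain fatty acids, total
# flavonoids and total carotenoids are excluded, as are the processing and
# phytochemical domains; red and processed meats are separate attributes.
.fcs_attribute_spec <- function() {
  spec <- rbind(
    c("fiber_carb_ratio",        "nutrient ratios", 1, 0.10),
    c("potassium_sodium_ratio",  "nutrient ratios", 1, 2),
    c("added_sugar_carb_ratio",  "nutrient ratios", -1, 0.20),
    c("unsat_sat_fat_ratio",     "nutrient ratios", 1, 2),
    c("vitamin_a_ug",  "vitamins", 1, 100),
    c("vitamin_c_mg",  "vitamins", 1, 10),
    c("vitamin_d_ug",  "vitamins", 1, 1),
    c("vitamin_e_mg",  "vitamins", 1, 1.5),
    c("vitamin_k_ug",  "vitamins", 1, 15),
    c("thiamin_mg",    "vitamins", 1, 0.1),
    c("riboflavin_mg", "vitamins", 1, 0.1),
    c("niacin_mg",     "vitamins", 1, 1.5),
    c("vitamin_b6_mg", "vitamins", 1, 0.15),
    c("folate_ug",     "vitamins", 1, 30),
    c("vitamin_b12_ug","vitamins", 1, 0.2),
    c("choline_mg",    "vitamins", 1, 30),
    c("calcium_mg",    "minerals", 1, 100),
    c("iron_mg",       "minerals", 1, 1.2),
    c("magnesium_mg",  "minerals", 1, 30),
    c("potassium_mg",  "minerals", 1, 300),
    c("zinc_mg",       "minerals", 1, 1),
    c("phosphorus_mg", "minerals", 1, 100),
    c("selenium_ug",   "minerals", 1, 5),
    c("copper_mg",     "minerals", 1, 0.1),
    c("manganese_mg",  "minerals", 1, 0.2),
    c("fruits",          "food ingredients", 1, 40),
    c("vegetables",      "food ingredients", 1, 60),
    c("legumes",         "food ingredients", 1, 20),
    c("whole_grains",    "food ingredients", 1, 15),
    c("nuts_seeds",      "food ingredients", 1, 5),
    c("seafood",         "food ingredients", 1, 10),
    c("red_meats",       "food ingredients", -1, 10),
    c("processed_meats", "food ingredients", -1, 5),
    c("refined_grains",  "food ingredients", -1, 15),
    c("ssb",             "food ingredients", -1, 50),
    c("added_sugar_g",            "additives", -1, 5),
    c("additive_sodium_mg",       "additives", -1, 300),
    c("artificial_sweetener_mg",  "additives", -1, 10),
    c("cholesterol_mg", "specific lipids", -1, 30),
    c("ala_g",          "specific lipids", 1, 0.2),
    c("epa_mg",         "specific lipids", 1, 50),
    c("dha_mg",         "specific lipids", 1, 50),
    c("protein_g",       "protein & fiber", 1, 5),
    c("plant_protein_g", "protein & fiber", 1, 3),
    c("fiber_g",         "protein & fiber", 1, 2),
    c("soluble_fiber_g", "protein & fiber", 1, 0.5)
  )
  data.frame(name = spec[, 1], domain = spec[, 2],
             direction = as.numeric(spec[, 3]),
             ref = as.numeric(spec[, 4]), stringsAsFactors = FALSE)
}

#' Default (placeholder) Food Compass configuration
#'
#' The authoritative attribute cut-points belong to the original Food
#' Compass publication and are not redistributed here; this config carries
#' the correct attribute and domain structure (46 attributes, 7 domains,
#' red and processed meats separate, the excluded attributes absent) with
#' placeholder monotone ladders built from per-attribute reference scales.
#' It is suitable for testing pipeline structure, not for reproducing
#' published absolute scores.
#'
#' Each attribute ladder has breaks at 0.25/0.5/1/2 times the attribute's
#' reference scale and rung scores 0,2,5,8,10 (reversed for harmful
#' attributes). Ties at a cut-point resolve to the healthier side.
#'
#' @return List of class `fcs_config` with fields `attributes` (list of
#'   per-attribute definitions), `domains` and `scaling`
#'   (`upper` 26.1, `span` 36.7, `range` 99).
#' @export
default_fcs_config <- function() {
  spec <- .fcs_attribute_spec()
  attributes <- lapply(seq_len(nrow(spec)), function(i) {
    breaks <- spec$ref[i] * c(0.25, 0.5, 1, 2)
    # ingredient attributes enter the raw score as a sum over ten
    # attributes rather than through a domain mean, so their rungs are
    # kept small (0-2) to keep raw scores on the published scale
    scores <- if (spec$domain[i] == "food ingredients") {
      c(0L, 1L, 1L, 2L, 2L)
    } else {
      c(0L, 2L, 5L, 8L, 10L)
    }
    if (spec$direction[i] < 0) scores <- rev(scores)
    list(name = spec$name[i], domain = spec$domain[i],
         direction = spec$direction[i], breaks = breaks, scores = scores)
  })
  names(attributes) <- spec$name
  cfg <- structure(
    list(attributes = attributes, domains = .fcs_domains,
         scaling = list(upper = 26.1, span = 36.7, range = 99),
         authoritative = FALSE),
    class = "fcs_config"
  )
  validate_fcs_config(cfg)
}

#' Validate a Food Compass configuration
#'
#' @param cfg An `fcs_config`.
#' @return `cfg` if valid (46 attributes, 7 domains, excluded attributes
#'   absent, every ladder monotone along its direction).
#' @export
validate_fcs_config <- function(cfg) {
  stopifnot(inherits(cfg, "fcs_config"))
  if (length(cfg$attributes) != 46) {
    stop_dietshift("NON_MONOTONE_CUTPOINTS", "config must define 46 attributes, got %d",
                   length(cfg$attributes))
  }
  if (!setequal(cfg$domains, .fcs_domains)) {
    stop_dietshift("EMPTY_DOMAIN", "config must use exactly the 7 adapted domains")
  }
  excluded <- c("iodine", "trans_fat", "mcfa", "flavonoids", "carotenoids")
  if (any(vapply(cfg$attributes, `[[`, "", "name") %in% excluded)) {
    stop_dietshift("NON_MONOTONE_CUTPOINTS", "excluded attributes present in config")
  }
  for (a in cfg$attributes) {
    if (is.unsorted(a$breaks, strictly = TRUE)) {
      stop_dietshift("NON_MONOTONE_CUTPOINTS", "breaks not strictly increasing for %s", a$name)
    }
    if (length(a$scores) != length(a$breaks) + 1) {
      stop_dietshift("NON_MONOTONE_CUTPOINTS", "scores/breaks length mismatch for %s", a$name)
    }
    ord <- if (a$direction > 0) a$scores else rev(a$scores)
    if (is.unsorted(ord)) {
      stop_dietshift("NON_MONOTONE_CUTPOINTS",
                     "scores not monotone along direction for %s", a$name)
    }
  }
  cfg
}

# Ladder lookup for one attribute. Half-open intervals closed on the
# healthier side: for beneficial attributes a value equal to a cut-point
# takes the upper rung; for harmful ones it takes the lower (healthier)
# rung.
.ladder_score <- function(value, attr) {
  idx <- findInterval(value, attr$breaks, left.open = attr$direction < 0) + 1L
  attr$scores[idx]
}

#' Score every attribute of a per-100-kcal profile
#'
#' @param p A `nutrient_profile` (see [aggregate_profile()]) or a named
#'   numeric vector of per-100-kcal attribute values.
#' @param cfg An `fcs_config`.
#' @return Named integer vector of attribute scores. Attributes missing
#'   from the profile score 0 (mirroring the exclusion of unmeasured
#'   attributes) and are listed in the `"missing"` attribute.
#' @export
score_attributes <- function(p, cfg = default_fcs_config()) {
  validate_fcs_config(cfg)
  amounts <- if (inherits(p, "nutrient_profile")) p$amounts else as.list(p)
  out <- stats::setNames(integer(length(cfg$attributes)), names(cfg$attributes))
  missing <- character(0)
  for (a in cfg$attributes) {
    v <- amounts[[a$name]]
    if (is.null(v) || is.na(v)) {
      missing <- c(missing, a$name)
      out[a$name] <- 0L
    } else {
      out[a$name] <- .ladder_score(v, a)
    }
  }
  attr(out, "missing") <- missing
  out
}

#' Aggregate attribute scores into the raw Food Compass score
#'
#' Domain score = mean of the domain's attribute scores. The raw score is
#' the mean of the six non-ingredient domain scores plus the *sum* of the
#' food-ingredients attribute scores (the ingredients domain enters as a
#' sum, not through the mean).
#'
#' @param attribute_scores Named numeric vector from [score_attributes()].
#' @param cfg An `fcs_config`.
#' @return List with `raw`, `domain_scores` and `domain_contributions`
#'   (percent of the raw score attributable to each domain; `NA` when the
#'   raw score is not positive).
#' @export
raw_fcs <- function(attribute_scores, cfg = default_fcs_config()) {
  validate_fcs_config(cfg)
  dom_of <- vapply(cfg$attributes, `[[`, "", "domain")
  nm <- names(attribute_scores)
  stopifnot(!is.null(nm), all(nm %in% names(dom_of)))
  domain_scores <- vapply(cfg$domains, function(d) {
    members <- nm[dom_of[nm] == d]
    if (length(members) == 0) {
      stop_dietshift("EMPTY_DOMAIN", "domain '%s' has no scored attributes", d)
    }
    mean(attribute_scores[members])
  }, numeric(1))
  non_ing <- setdiff(cfg$domains, "food ingredients")
  ing_attrs <- nm[dom_of[nm] == "food ingredients"]
  raw <- mean(domain_scores[non_ing]) + sum(attribute_scores[ing_attrs])
  contrib <- rep(NA_real_, length(cfg$domains))
  names(contrib) <- cfg$domains
  if (raw > 0) {
    contrib[non_ing] <- domain_scores[non_ing] / length(non_ing) / raw * 100
    contrib["food ingredients"] <- sum(attribute_scores[ing_attrs]) / raw * 100
  }
  list(raw = raw, domain_scores = domain_scores, domain_contributions = contrib)
}

#' Rescale a raw Food Compass score to the 1-100 scale
#'
#' Applies the affine map `100 - (upper - raw) / span * range` with the
#' published constants upper = 26.1, span = 36.7, range = 99, so raw 26.1
#' maps to 100 and raw -10.6 maps to 1. No clamping: out-of-range raw
#' scores yield out-of-range scaled scores with a warning.
#'
#' @param raw Raw score (numeric vector ok).
#' @param cfg An `fcs_config` supplying the scaling constants.
#' @return Scaled score(s).
#' @export
scale_fcs <- function(raw, cfg = default_fcs_config()) {
  s <- cfg$scaling
  scaled <- 100 - (s$upper - raw) / s$span * s$range
  if (any(scaled < 1 - 1e-9 | scaled > 100 + 1e-9)) {
    warn_dietshift("FCS_OUT_OF_RANGE",
                   "scaled FCS outside [1, 100] for raw score(s): %s",
                   paste(format(raw[scaled < 1 | scaled > 100]), collapse = ", "))
  }
  scaled
}

#' Invert the Food Compass scaling
#'
#' @param scaled Scaled score(s).
#' @param cfg An `fcs_config`.
#' @return Raw score(s) mapping to `scaled` under [scale_fcs()].
#' @export
unscale_fcs <- function(scaled, cfg = default_fcs_config()) {
  s <- cfg$scaling
  s$upper - (100 - scaled) * s$span / s$range
}

#' Full Food Compass score card for a profile
#'
#' @param p A `nutrient_profile`.
#' @param cfg An `fcs_config`.
#' @return List of class `score_card`: `raw_fcs`, `scaled_fcs`,
#'   `domain_scores`, `domain_contributions`, `attribute_scores`.
#' @export
fcs_score <- function(p, cfg = default_fcs_config()) {
  scores <- score_attributes(p, cfg)
  agg <- raw_fcs(scores, cfg)
  structure(
    list(raw_fcs = agg$raw, scaled_fcs = scale_fcs(agg$raw, cfg),
         domain_scores = agg$domain_scores,
         domain_contributions = agg$domain_contributions,
         attribute_scores = scores),
    class = "score_card"
  )
}

#' Write / read an `fcs_config` as JSON
#'
#' @param cfg An `fcs_config`.
#' @param path File path.
#' @return `write_fcs_config` returns `path` invisibly; `read_fcs_config`
#'   returns a validated `fcs_config`.
#' @export
write_fcs_config <- function(cfg, path) {
  validate_fcs_config(cfg)
  jsonlite::write_json(
    list(attributes = unname(cfg$attributes), domains = cfg$domains,
         scaling = cfg$scaling, authoritative = isTRUE(cfg$authoritative)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fcs_config
#' @export
read_fcs_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  attributes <- lapply(x$attributes, function(a) {
    list(name = a$name, domain = a$domain, direction = a$direction,
         breaks = as.numeric(unlist(a$breaks)),
         scores = as.integer(unlist(a$scores)))
  })
  names(attributes) <- vapply(attributes, `[[`, "", "name")
  validate_fcs_config(structure(
    list(attributes = attributes, domains = unlist(x$domains),
         scaling = as.list(unlist(x$scaling)),
         authoritative = isTRUE(x$authoritative)),
    class = "fcs_config"))
}
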