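# Core domain model: the closed 14-food-group vocabulary, diet compositions
# (mass shares of a fixed-total-mass daily diet) and consumption models.

#' The 14 food groups of the composite-diet model
#'
#' The composite daily diet is partitioned into a closed set of 14 food
#' groups. Group membership is case-insensitive and a few common synonyms
#' ("fish", "processed meats", ...) are accepted on input; the canonical
#' labels below are used everywhere else.
#'
#' @return Character vector of the 14 canonical group labels.
#' @export
food_groups <- function() {
  c(
    "whole grains", "refined grains", "nuts", "legumes", "fruits",
    "vegetables", "fish/seafood", "red meat", "processed meat",
    "white meat", "dairy", "eggs", "added oils", "sugar-sweetened beverages"
  )
}

# Synonyms accepted on input, mapped to canonical labels.
.group_synonyms <- c(
  "fish"                 = "fish/seafood",
  "seafood"              = "fish/seafood",
  "processed meats"      = "processed meat",
  "red meats"            = "red meat",
  "white meats"          = "white meat",
  "whole grain"          = "whole grains",
  "refined grain"        = "refined grains",
  "nuts and seeds"       = "nuts",
  "milk"                 = "dairy",
  "ssb"                  = "sugar-sweetened beverages",
  "sugar sweetened beverages" = "sugar-sweetened beverages"
)

#' Canonicalize food-group labels
#'
#' @param x Character vector of group labels (any case, known synonyms ok).
#' @return Character vector of canonical labels.
#' @export
canonical_group <- function(x) {
  lx <- tolower(trimws(x))
  mapped <- ifelse(lx %in% names(.group_synonyms), .group_synonyms[lx], lx)
  bad <- !(mapped %in% food_groups())
  if (any(bad)) {
    stop_dietshift("UNKNOWN_GROUP", "unknown food group(s): %s",
                   paste(unique(x[bad]), collapse = ", "))
  }
  unname(mapped)
}

#' Construct a diet composition
#'
#' A diet composition assigns each food group a fraction of the diet's
#' total daily mass. The default total mass is 1800 g, the baseline daily
#' weight shared by the current, feasible and optimal anchor diets. Groups
#' omitted from `shares` get share 0.
#'
#' @param shares Named numeric vector: food group -> mass fraction.
#'   Fractions must be non-negative and sum to 1 (tolerance 1e-9).
#' @param total_mass_g Total daily diet mass in grams (default 1800).
#' @param percent If `TRUE`, `shares` are given in percent of mass and are
#'   divided by 100 on input.
#' @return A validated object of class `diet_composition`.
#' @export
diet_composition <- function(shares, total_mass_g = 1800, percent = FALSE) {
  if (is.null(names(shares)) || any(!nzchar(names(shares)))) {
    stop_dietshift("UNKNOWN_GROUP", "shares must be a fully named vector")
  }
  nm <- canonical_group(names(shares))
  if (anyDuplicated(nm)) {
    stop_dietshift("UNKNOWN_GROUP", "duplicated food group(s): %s",
                   paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  full <- stats::setNames(numeric(length(food_groups())), food_groups())
  full[nm] <- as.numeric(shares)
  if (percent) full <- full / 100
  obj <- structure(
    list(shares = full, total_mass_g = total_mass_g),
    class = "diet_composition"
  )
  validate_composition(obj)
}

#' Validate a diet composition
#'
#' Checks the composition invariants: a complete share map over the 14
#' groups, no negative share, shares summing to 1 within 1e-9 and a
#' positive total mass.
#'
#' @param c A `diet_composition`.
#' @return `c`, unchanged, if all invariants hold.
#' @export
validate_composition <- function(c) {
  if (!inherits(c, "diet_composition") || is.null(c$shares)) {
    stop_dietshift("UNKNOWN_GROUP", "not a diet_composition with a share map")
  }
  if (!setequal(names(c$shares), food_groups())) {
    stop_dietshift("UNKNOWN_GROUP", "share map must cover exactly the 14 food groups")
  }
  if (any(c$shares < 0)) {
    neg <- names(c$shares)[c$shares < 0]
    stop_dietshift("NEGATIVE_SHARE", "negative share(s) for: %s",
                   paste(neg, collapse = ", "))
  }
  s <- sum(c$shares)
  if (abs(s - 1) > 1e-9) {
    stop_dietshift("SUM_NOT_ONE",
                   "shares sum to %.12g (deviation %+.3g from 1)", s, s - 1)
  }
  if (!is.numeric(c$total_mass_g) || length(c$total_mass_g) != 1 ||
      !is.finite(c$total_mass_g) || c$total_mass_g <= 0) {
    stop_dietshift("SUM_NOT_ONE", "total_mass_g must be a positive finite scalar")
  }
  c
}

#' Daily mass of one food group in a diet
#'
#' @param c A validated `diet_composition`.
#' @param g Food-group label (canonical or synonym).
#' @return Mass in grams: `share * total_mass_g`.
#' @export
grams_of <- function(c, g) {
  validate_composition(c)
  g <- canonical_group(g)
  unname(c$shares[g] * c$total_mass_g)
}

#' @export
print.diet_composition <- function(x, ...) {
  cat(sprintf("<diet_composition> total mass %.0f g\n", x$total_mass_g))
  nz <- x$shares[x$shares > 0]
  for (g in names(nz)) {
    cat(sprintf("  %-26s %6.2f %%  (%7.1f g)\n", g, 100 * nz[g],
                nz[g] * x$total_mass_g))
  }
  invisible(x)
}

#' Consumption models: which meats are replaced by legumes
#'
#' Model M1 targets red meat only; M2 targets red and white meat; M3
#' targets red, white and processed meat.
#'
#' @param model_id One of "M1", "M2", "M3".
#' @return List with `model_id` and `targeted_groups`.
#' @export
consumption_model <- function(model_id = c("M1", "M2", "M3")) {
  model_id <- match.arg(model_id)
  targeted <- switch(model_id,
    M1 = "red meat",
    M2 = c("red meat", "white meat"),
    M3 = c("red meat", "white meat", "processed meat")
  )
  structure(list(model_id = model_id, targeted_groups = targeted),
            class = "consumption_model")
}
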