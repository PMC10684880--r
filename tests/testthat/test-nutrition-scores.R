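one_food_table <- function(kcal, fiber = 0, group = "legumes", ...) {
  extra <- c(...)
  df <- data.frame(food_id = "f1", group = group, kcal_per_100g = kcal,
                   fiber_g = fiber, stringsAsFactors = FALSE)
  for (n in names(extra)) df[[n]] <- extra[n]
  df
}

test_that("single-food profiles rescale to the 100 kcal basis", {
  comp <- diet_composition(c(legumes = 1))
  foods <- one_food_table(kcal = 50, fiber = 2)
  out <- aggregate_profile(comp, foods)
  # 1800 g at 50 kcal / 2 g fiber per 100 g: 900 kcal, 36 g fiber per day
  expect_equal(out$profile$total_kcal_per_day, 900)
  expect_equal(out$profile$amounts$fiber_g, 4)
  expect_equal(unname(out$risks["Fiber"]), 4)
  # the ingredient attribute carries grams of the group per 100 kcal
  expect_equal(out$profile$amounts$legumes, 1800 * 100 / 900)
})

test_that("profiles are mass-weighted sums over ingredients", {
  w <- test_world()
  comp <- quick_comp("legumes" = 30, "red meat" = 20)
  out <- aggregate_profile(comp, w$foods, w$food_map)

  # brute-force per-ingredient oracle, explicit loops
  kcal <- 0
  fiber <- 0
  for (g in names(comp$shares)[comp$shares > 0]) {
    grams <- comp$shares[[g]] * 1800
    row <- w$foods[w$foods$group == g, ]
    kcal <- kcal + grams * row$kcal_per_100g / 100
    fiber <- fiber + grams * row$fiber_g / 100
  }
  expect_equal(out$profile$total_kcal_per_day, kcal)
  expect_equal(out$profile$amounts$fiber_g, fiber * 100 / kcal)
})

test_that("energy-free and unmapped diets raise coded errors", {
  comp <- diet_composition(c(legumes = 1))
  expect_error(aggregate_profile(comp, one_food_table(kcal = 0)),
               class = "ZERO_ENERGY_DIET")
  expect_error(
    aggregate_profile(comp, one_food_table(kcal = 50, group = "fruits")),
    class = "MISSING_FOOD")
})

test_that("heni_score evaluates the published factor model", {
  t <- heni_factors()
  zero <- stats::setNames(rep(0, 15), t$risk)
  expect_equal(heni_score(zero), 0)

  red <- zero
  red["Red meats"] <- 1
  expect_equal(heni_score(red), -0.53 * 0.0990)

  sea <- zero
  sea["Seafood"] <- 1
  expect_equal(heni_score(sea), 42.93)

  bad <- zero
  names(bad)[1] <- "Potassium"
  expect_error(heni_score(bad), class = "KEY_MISMATCH")
})

test_that("heni_score is linear and additive in intakes", {
  t <- heni_factors()
  set.seed(11)
  for (i in 1:10) {
    d <- stats::setNames(stats::rexp(15), t$risk)
    a <- stats::runif(1, 0, 4)
    expect_equal(heni_score(a * d), a * heni_score(d), tolerance = 1e-12)
    mask <- sample(c(TRUE, FALSE), 15, replace = TRUE)
    d1 <- d2 <- stats::setNames(rep(0, 15), t$risk)
    d1[mask] <- d[mask]
    d2[!mask] <- d[!mask]
    expect_equal(heni_score(d1) + heni_score(d2), heni_score(d),
                 tolerance = 1e-12)
  }
})

test_that("swapping processed meat for legumes gains the expected minutes", {
  t <- heni_factors()
  base <- stats::setNames(stats::rexp(15) + 1, t$risk)
  swapped <- base
  swapped["Processed meats"] <- swapped["Processed meats"] - 1
  swapped["Legumes"] <- swapped["Legumes"] + 1
  gain <- heni_score(swapped, t) - heni_score(base, t)
  expect_equal(gain, -0.53 * (-0.23 - 0.86), tolerance = 1e-12)
  expect_gt(gain, 0)
})

test_that("cut-point ladders score with ties on the healthier side", {
  ladder <- list(name = "x", domain = "minerals", direction = 1,
                 breaks = c(1, 2), scores = c(0L, 5L, 10L))
  score1 <- function(v, a) dietshift:::.ladder_score(v, a)
  expect_equal(score1(0.5, ladder), 0)  # below the first cut-point
  expect_equal(score1(1.5, ladder), 5)  # inside 1-2 g
  expect_equal(score1(2.5, ladder), 10)
  expect_equal(score1(1, ladder), 5)    # tie: upper rung for beneficial
  expect_equal(score1(2, ladder), 10)

  harmful <- list(name = "y", domain = "additives", direction = -1,
                  breaks = c(1, 2), scores = c(10L, 5L, 0L))
  expect_equal(score1(1, harmful), 10)  # tie: healthier (lower) side
  expect_equal(score1(1.5, harmful), 5)
  expect_equal(score1(2, harmful), 5)
})

test_that("score_attributes covers the config and logs missing attributes", {
  cfg <- default_fcs_config()
  expect_length(cfg$attributes, 46)
  expect_length(cfg$domains, 7)
  scores <- score_attributes(c(fiber_g = 2, calcium_mg = 100), cfg)
  expect_length(scores, 46)
  expect_true(all(scores[setdiff(names(scores),
                                 c("fiber_g", "calcium_mg"))] == 0))
  expect_length(attr(scores, "missing"), 44)
})

test_that("non-monotone cut-point configs are rejected", {
  cfg <- default_fcs_config()
  cfg$attributes$fiber_g$scores <- c(0L, 5L, 3L, 8L, 10L)
  expect_error(validate_fcs_config(cfg), class = "NON_MONOTONE_CUTPOINTS")
  cfg2 <- default_fcs_config()
  cfg2$attributes$fiber_g$breaks <- c(2, 1, 3, 4)
  expect_error(validate_fcs_config(cfg2), class = "NON_MONOTONE_CUTPOINTS")
})

test_that("raw FCS is mean-of-domains plus the ingredient sum", {
  cfg <- default_fcs_config()
  dom_of <- vapply(cfg$attributes, `[[`, "", "domain")
  scores <- stats::setNames(rep(0L, 46), names(cfg$attributes))
  expect_equal(raw_fcs(scores, cfg)$raw, 0)

  # six non-ingredient domains at 1, two ingredient attributes 2 and 3
  scores[dom_of[names(scores)] != "food ingredients"] <- 1L
  ing <- names(scores)[dom_of[names(scores)] == "food ingredients"]
  scores[ing[1:2]] <- c(2L, 3L)
  expect_equal(raw_fcs(scores, cfg)$raw, 1 + 5)

  # a single nonzero ingredient attribute passes through
  scores[] <- 0L
  scores[ing[3]] <- 4L
  expect_equal(raw_fcs(scores, cfg)$raw, 4)
})

test_that("raw FCS equals a brute-force recomputation on random scores", {
  cfg <- default_fcs_config()
  dom_of <- vapply(cfg$attributes, `[[`, "", "domain")
  set.seed(99)
  for (i in 1:10) {
    scores <- stats::setNames(sample(0:10, 46, replace = TRUE),
                              names(cfg$attributes))
    got <- raw_fcs(scores, cfg)
    doms <- unique(dom_of)
    dsum <- dcount <- stats::setNames(numeric(length(doms)), doms)
    for (a in names(scores)) {
      dsum[dom_of[a]] <- dsum[dom_of[a]] + scores[a]
      dcount[dom_of[a]] <- dcount[dom_of[a]] + 1
    }
    dmean <- dsum / dcount
    non_ing <- setdiff(doms, "food ingredients")
    expected <- sum(dmean[non_ing]) / length(non_ing) + dsum["food ingredients"]
    expect_equal(got$raw, unname(expected))
    expect_equal(got$domain_scores[doms], dmean[doms])
    if (got$raw > 0) {
      expect_equal(sum(got$domain_contributions), 100, tolerance = 0.01)
    }
  }
})

test_that("the FCS scaling is the published affine map with fixed points", {
  cfg <- default_fcs_config()
  expect_equal(scale_fcs(26.1, cfg), 100)
  expect_equal(scale_fcs(-10.6, cfg), 1)
  # raw score recovering the published current-diet scaled score
  expect_equal(scale_fcs(unscale_fcs(65.46, cfg), cfg), 65.46,
               tolerance = 1e-9)
  expect_equal(unscale_fcs(65.46, cfg), 13.2955, tolerance = 1e-4)
  # strictly increasing, affine, no clamping (warns out of range)
  r <- seq(-20, 40, by = 0.5)
  s <- suppressWarnings(scale_fcs(r, cfg))
  expect_true(all(diff(s) > 0))
  expect_equal(diff(s) / diff(r), rep(99 / 36.7, length(r) - 1))
  expect_warning(scale_fcs(30, cfg), class = "FCS_OUT_OF_RANGE")
})

test_that("risk contributions are normalized absolute factor products", {
  t <- heni_factors()
  zero <- stats::setNames(rep(0, 15), t$risk)
  expect_error(risk_contributions(zero), class = "ALL_ZERO")

  single <- zero
  single["Fruits"] <- 2
  expect_equal(unname(risk_contributions(single)["Fruits"]), 100)

  # two risks with equal |factor * d| split 50/50
  pair <- zero
  pair["Fruits"] <- 1 / 0.18
  pair["Sodium"] <- 1 / 13.9
  got <- risk_contributions(pair)
  expect_equal(unname(got[c("Fruits", "Sodium")]), c(50, 50))

  # |products| 1, 2, 2 -> 20 / 40 / 40
  trio <- zero
  trio["Fruits"] <- 1 / 0.18
  trio["Sodium"] <- 2 / 13.9
  trio["Legumes"] <- 2 / 0.23
  got <- risk_contributions(trio)
  expect_equal(unname(got[c("Fruits", "Sodium", "Legumes")]), c(20, 40, 40))
  expect_equal(sum(got), 100)
})
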