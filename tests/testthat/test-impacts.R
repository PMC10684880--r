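test_that("per-gram factors divide the RACC mean by the RACC mass", {
  expect_equal(per_gram_factor(0.50, 100), 0.005)
  expect_equal(per_gram_factor(0, 85), 0)
  expect_error(per_gram_factor(1, 0), class = "ZERO_RACC")
})

test_that("diet impacts sum per-gram factors times ingredient masses", {
  # one ingredient at 250 g with a 0.005/g factor on every indicator
  t <- data.frame(
    food_id = "leg", racc_g = 100, indicator = impact_indicators(),
    unit = "u", mean_per_racc = 0.5, stringsAsFactors = FALSE)
  fm <- data.frame(group = "legumes", food_id = "leg",
                   stringsAsFactors = FALSE)
  comp <- quick_comp("legumes" = 250 / 18)
  t2 <- rbind(t, data.frame(food_id = "rg", racc_g = 50,
                            indicator = impact_indicators(), unit = "u",
                            mean_per_racc = 0, stringsAsFactors = FALSE))
  fm2 <- rbind(fm, data.frame(group = "refined grains", food_id = "rg"))
  v <- diet_impacts(comp, t2, fm2)
  expect_equal(unname(v["global warming short term"]), 250 * 0.005)
  expect_equal(attr(v, "basis"), "per-diet-day")

  # a diet of two ingredients equals the sum of the single-ingredient diets
  w <- test_world()
  ab <- quick_comp("legumes" = 20, "red meat" = 10)
  a <- quick_comp("legumes" = 20)
  b <- quick_comp("red meat" = 10)
  filler <- quick_comp()
  va <- diet_impacts(a, w$impact_factors, w$food_map)
  vb <- diet_impacts(b, w$impact_factors, w$food_map)
  vf <- diet_impacts(filler, w$impact_factors, w$food_map)
  vab <- diet_impacts(ab, w$impact_factors, w$food_map)
  expect_equal(unclass(vab), unclass(va) + unclass(vb) - unclass(vf),
               tolerance = 1e-12)
})

test_that("diet impacts match a brute-force loop oracle on the world", {
  w <- test_world()
  comp <- build_scenarios(w$anchors)$S5$composition
  got <- diet_impacts(comp, w$impact_factors, w$food_map)
  for (ind in impact_indicators()) {
    total <- 0
    for (g in food_groups()) {
      grams <- comp$shares[[g]] * comp$total_mass_g
      if (grams == 0) next
      fid <- w$food_map$food_id[w$food_map$group == g]
      row <- w$impact_factors[w$impact_factors$food_id == fid &
                                w$impact_factors$indicator == ind, ]
      total <- total + grams * row$mean_per_racc / row$racc_g
    }
    expect_equal(unname(got[ind]), total, tolerance = 1e-12, label = ind)
  }
})

test_that("missing factors and unit metadata are handled", {
  w <- test_world()
  no_legumes <- w$impact_factors[
    !w$impact_factors$food_id %in%
      w$food_map$food_id[w$food_map$group == "legumes"], ]
  comp <- quick_comp("legumes" = 10)
  fm <- w$food_map[w$food_map$group != "legumes", ]
  expect_error(diet_impacts(comp, no_legumes, fm), class = "MISSING_FACTOR")

  v <- diet_impacts(comp, w$impact_factors, w$food_map)
  units <- attr(v, "units")
  expect_equal(unname(units["global warming short term"]), "kg CO2 eq")
  expect_equal(unname(units["fossil energy use"]), "MJ")
  v100 <- normalize_per_100kcal(v, 2000)
  expect_identical(attr(v100, "units"), units)
})

test_that("per-100-kcal rebasing scales by 100 over the daily energy", {
  t <- data.frame(food_id = "leg", racc_g = 100,
                  indicator = impact_indicators(), unit = "u",
                  mean_per_racc = 0.5, stringsAsFactors = FALSE)
  v <- structure(stats::setNames(rep(2, 18), impact_indicators()),
                 basis = "per-diet-day",
                 units = stats::setNames(rep("u", 18), impact_indicators()),
                 class = c("impact_vector", "numeric"))
  v100 <- normalize_per_100kcal(v, 2000)
  expect_equal(unname(v100["water use"]), 0.10)
  expect_equal(attr(v100, "basis"), "per-100-kcal")
  expect_equal(as.numeric(normalize_per_100kcal(v, 100)), as.numeric(v))
  expect_error(normalize_per_100kcal(v, 0), class = "ZERO_ENERGY")
})

test_that("percent_change reports reductions relative to baseline", {
  expect_equal(percent_change(0.20, 0.10), 50)
  expect_equal(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), class = "ZERO_BASELINE")
})

test_that("1:1 meat-to-legume swaps reduce meat-dominated indicators", {
  w <- test_world()
  gw <- "global warming short term"
  fac <- function(group) {
    fid <- w$food_map$food_id[w$food_map$group == group]
    row <- w$impact_factors[w$impact_factors$food_id == fid &
                              w$impact_factors$indicator == gw, ]
    row$mean_per_racc / row$racc_g
  }
  for (meat in c("red meat", "processed meat", "white meat")) {
    expect_gt(fac(meat), fac("legumes"))
    base <- quick_comp(stats::setNames(10, meat))
    swap <- quick_comp(stats::setNames(5, meat), "legumes" = 5)
    # refined-grain filler identical in both diets by construction
    expect_equal(base$shares[["refined grains"]],
                 swap$shares[["refined grains"]])
    vb <- diet_impacts(base, w$impact_factors, w$food_map)
    vs <- diet_impacts(swap, w$impact_factors, w$food_map)
    expect_lt(unname(vs[gw]), unname(vb[gw]))
  }
})
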