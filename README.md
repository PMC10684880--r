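# dietshift

Sustainable-diet modelling of a gradual meat-to-legume transition:
nutritional quality versus environmental footprint of composite daily
diets.

Dietary guidance usually evaluates single foods; people eat composite
diets. `dietshift` models a fixed-mass (1.8 kg/day) daily diet over 14
food groups as it transitions from a current Western-style pattern
toward an optimal plant-forward pattern, and asks where along that
transition the nutrition-environment trade-off is best. It is written
for nutrition and food-sustainability researchers who want the whole
chain - scenario design, diet-quality scoring, life-cycle footprint
aggregation, trade-off statistics - as tested, reusable functions
rather than spreadsheet arithmetic.

## The model

**Scenario design.** Three anchor diets - current (S1), optimal (S10)
and feasible (S5, the per-group midpoint of the other two) - plus
intermediate scenarios S2-S4 and S6-S9 under three consumption models:
M1 replaces red meat with legumes, M2 also white meat, M3 also
processed meat (1:1 by mass, total fixed at 1800 g/day). With the
anchors shared across models this yields 24 scenarios.

**Nutritional quality**, per 100 kcal, on two systems:

- HENI (Health Nutritional Index), in minutes of healthy life:

      HENI = -0.53 * Σ_r  HENIFactor_r · d_r

  over 15 Global-Burden-of-Disease dietary risks *r* with intake
  *d_r* per 100 kcal (beneficial risks carry negative factors, e.g.
  seafood -81.000; harmful positive, e.g. sodium +13.9).

- An adapted Food Compass Score: 46 attributes in 7 domains scored on
  monotone cut-point ladders; raw score = mean of the six non-ingredient
  domain scores + sum of the food-ingredient attribute scores, rescaled
  by

      FCS = 100 - (26.1 - raw) / 36.7 * 99

  so raw 26.1 maps to 100 and raw -10.6 maps to 1.

**Environmental footprint.** 18 life-cycle midpoint indicators (global
warming short/long term, water use, ionizing radiation, eutrophication,
acidification, toxicity, land occupation, ...). Per-food mean impacts
per serving (RACC) are divided by the RACC mass into per-gram factors;
diet impacts are ingredient-mass-weighted sums, reported per diet-day
and per 100 kcal.

**Trade-off statistics.** Pearson correlations, subgroup means with
sample SDs, strict threshold counts, tie-averaged ranks with the
tie-corrected Kruskal-Wallis H, and Pareto (non-dominance) flags on
joint (nutrition score, impact) axes.

Because the authoritative Food Compass cut-points and the study's
per-food factor workbooks are external, absolute published scores are
carried as verbatim checksummed fixtures (`table1_scores()`,
`heni_factors()`, `printed_compositions()`); everything recomputable
from them is recomputed, and a seeded synthetic world
(`generate_foods()`, `generate_anchors()`) with the assumed statistical
structure exercises every other stage end to end.

## Worked example

```r
library(dietshift)

anchors   <- generate_anchors()                      # fixed study anchors
world     <- generate_foods(synth_config(seed = 20231128))
scenarios <- build_scenarios(anchors)                # 24 scenarios
scenarios$S9M3$composition
#> <diet_composition> total mass 1800 g
#>   whole grains                 7.64 %  (  137.5 g)
#>   refined grains               9.73 %  (  175.1 g)
#>   nuts                         1.67 %  (   30.1 g)
#>   legumes                     10.00 %  (  180.0 g)
#>   ...
```

S9M3 is the scenario with 10% legumes, 0.28% processed, 0.11% red and
2.81% white meat - about three quarters of all meat mass replaced.
Scoring the whole set on the synthetic world:

```r
scores <- score_scenarios(scenarios, world$foods,
                          world$impact_factors, world$food_map)
scores[scores$scenario_id %in% c("S1", "S5", "S9M3", "S10"),
       c("scenario_id", "total_kcal", "scaled_fcs", "heni_minutes",
         "per100kcal.global warming short term")]
#>  scenario_id total_kcal scaled_fcs heni_minutes per100kcal.gw.short
#>           S1       2696      61.38        40.08              0.1990
#>           S5       2602      76.84       189.06              0.1608
#>         S9M3       2479      79.39       199.45              0.1146
#>          S10       2508      86.94       349.22              0.1198
```

Nutrition scores rise monotonically toward the optimal diet, while
global warming per 100 kcal reaches its *minimum* at S9M3 and rises
again at S10 (the optimal diet's large fruit/vegetable/fish masses cost
more than the meat it removes) - so S9M3, not S10, is Pareto-optimal on
the (FCS, global warming) axes:

```r
gw <- setNames(scores[["perday.global warming short term"]],
               scores$scenario_id)
percent_change(gw[["S1"]], gw[["S9M3"]])
#> 47.05   # percent reduction, synthetic factor tables

tt <- tradeoff_table(scores, "scaled_fcs",
                     "per100kcal.global warming short term")
tt$scenario_id[tt$pareto]
#> "S9M3" "S10"
```

The statistics over the published 24-scenario score table recompute
from the packaged fixture:

```r
head(reproduce_study_stats(), 4)
#>                     statistic    value
#>  fcs_mean_current_to_feasible 71.86400
#>    fcs_sd_current_to_feasible  2.36689
#>  fcs_mean_feasible_to_optimal 73.52000
#>    fcs_sd_feasible_to_optimal  0.62636
```

## Analysis workflow

The `analysis/` scripts run the full study pipeline in order, writing
tables under `results/`:

```sh
Rscript analysis/01_build_scenarios.R       # 24 compositions, both modes
Rscript analysis/02_score_scenarios.R       # HENI, FCS, 18 indicators
Rscript analysis/03_tradeoff_analysis.R     # Pareto flags, correlations
Rscript analysis/04_published_table_stats.R # fixture statistics
```

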