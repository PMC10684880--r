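---
title: "Modelling nutrition-environment trade-offs of meat-to-legume diet substitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nutrition-environment trade-offs of meat-to-legume diet substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

## The model

A composite daily diet is a mass partition of a fixed 1800 g/day intake
over 14 food groups (whole and refined grains, nuts, legumes, fruits,
vegetables, fish/seafood, red/processed/white meat, dairy, eggs, added
oils, sugar-sweetened beverages). Three anchor diets span the design:
the *current* diet (S1), an *optimal* plant-forward diet (S10), and the
*feasible* diet (S5), defined as the per-group arithmetic midpoint of
the other two. Between the anchors, seven intermediate scenarios (S2-S4,
S6-S9) partially replace meat mass 1:1 with legumes under three
consumption models: M1 replaces red meat only, M2 red and white meat,
M3 red, white and processed meat. Since S1, S5 and S10 are
model-independent, the design holds 3 + 7 x 3 = 24 distinct scenarios.

Each scenario is scored on three axes:

* **HENI** (Health Nutritional Index): healthy-life minutes per 100 kcal,
  `heni = -0.53 * sum_r factor_r * d_r`, where `d_r` is the intake of
  dietary risk `r` per 100 kcal and `factor_r` is the DALY-scale risk
  factor for the 15 Global-Burden-of-Disease dietary risks (9 food
  groups, 6 nutrients). Negative factors are beneficial; seafood
  (-81.000) is the largest-magnitude beneficial factor, sodium (+13.9)
  the most harmful. The packaged factor table is data, not code.
* **Adapted Food Compass Score**: 46 attributes in 7 domains scored on
  monotone cut-point ladders against the per-100-kcal profile; the raw
  score is the mean of the six non-ingredient domain scores plus the
  *sum* of the food-ingredient attribute scores, rescaled by the affine
  map `scaled = 100 - (26.1 - raw) / 36.7 * 99` (raw 26.1 -> 100,
  raw -10.6 -> 1; no clamping, out-of-range values warn).
* **Environmental footprint**: 18 life-cycle midpoint indicators. Each
  food's mean impact per serving (RACC, reference amount customarily
  consumed) is divided by the RACC mass to give a per-gram factor;
  a diet's impact is the ingredient-mass-weighted sum, reported per
  diet-day and per 100 kcal.

The trade-off layer provides Pearson correlations, subgroup mean/SD
summaries (sample, n-1, SD throughout - the published subgroup SDs only
recompute under the sample convention), strict threshold counts,
tie-averaged ranks with the tie-corrected Kruskal-Wallis H, and Pareto
(non-dominance) flags over joint (nutrition, impact) axes.

## Scenario construction: override and linear modes

The study that motivated this package derived its intermediate
compositions with irregular, hand-tuned steps that were published only in
a supplementary workbook; the main text prints the four targeted-group
shares (legumes, processed, red, white meat) for ten of the 24
scenarios. The builder therefore defaults to **override mode**: the
printed targeted shares are pinned exactly (packaged in
`printed_compositions()`), non-targeted groups sit at the feasible
anchor's values for S2-S9, refined grains absorbs the residual so every
scenario sums to exactly 1800 g, and the unprinted scenarios are filled
by the linear rule below (flagged `linear-fill` in
`printed_schedule()`). This never presents an approximation as the
published design where the design is known.

**Linear mode** is the documented convenience approximation: targeted
meat shares interpolate linearly along each segment (S1->S5 over steps
1/4..3/4, S5->S10 over 1/5..4/5), the removed meat mass is credited 1:1
to legumes, and all other groups are handled as in override mode. Within
a segment the refined-grain residual is constant, so moving along a
ladder changes only targeted meats (down) and legumes (up) - which is
what makes the monotonicity properties below provable rather than
incidental.

Anchors: the targeted-group anchor shares are fixed study conditions
(current 0% legumes / 2.78% processed / 5.56% red / 4.17% white;
optimal 11.11% / 0% / 0% / 2.78%). The ten non-targeted groups' anchor
shares were not printed; `generate_anchors()` ships one realistic
default (e.g. a current diet heavy in refined grains, dairy and
sugar-sweetened beverages; an optimal diet heavy in fruits, vegetables,
whole grains and fish, with oils and sugared beverages at zero), chosen
once and not tuned thereafter. The feasible anchor is always the
computed midpoint, so `check_anchor_midpoint()` reports zero deviation
by construction; with user-supplied anchors it reports per-group
deviations in percent-of-mass units against a 0.01 pp tolerance.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `total_mass_g` | 1800 | g/day | fixed composite-diet mass |
| HENI minutes constant | -0.53 | min per factor-unit | DALY-scale to minutes |
| FCS scaling | 26.1 / 36.7 / 99 | score units | affine 1-100 rescale |
| `meat_to_legume_ghg_ratio` | 5 | - | enforced per-gram GW separation |
| `noise_cv` | 0.15 | - | lognormal jitter CV |
| `seed` | 20231128 | - | generator reproducibility |
| midpoint tolerance | 0.01 | pp | feasible-anchor check |

The ratio default of 5 is a conservative stand-in for the per-gram
greenhouse-gas gap between animal meats and pulses reported across food
LCA compilations (beef alone is often 20x). Raising it widens the
ladder's environmental gradient but changes no qualitative conclusion;
the generator enforces the constraint after jitter, so it holds for
every seed.

## HENI intake units

The published factor table omits intake units, and the magnitude of the
seafood factor suggests per-serving scaling for some food-group rows.
Following the packaged table's declaration, all factors are applied per
gram (per 100 kcal); the `intake_unit` column is data, so a corrected
unit set drops in without code change. Under the per-gram default the
seafood term dominates synthetic-world HENI levels; ladder
*differences*, which drive every test and ranking here, are unaffected
in sign. Absolute synthetic HENI minutes should not be compared with
published values for this reason.

## The Food Compass configuration is a placeholder

The authoritative attribute cut-points belong to the original Food
Compass publication and are not redistributed. `default_fcs_config()`
carries the correct structure - 46 attributes in 7 domains (nutrient
ratios, vitamins, minerals, food ingredients, additives, specific
lipids, protein & fiber), red and processed meats as separate
attributes, iodine/trans-fat/medium-chain-fatty-acid/flavonoid/
carotenoid attributes absent - with placeholder ladders: breaks at
0.25/0.5/1/2 times a per-attribute reference scale and rungs 0/2/5/8/10
(0/1/1/2/2 for ingredient attributes, which enter the raw score as a
ten-attribute sum rather than through a domain mean, keeping raw scores
on the published scale). Ties at a cut-point resolve to the healthier
side (beneficial attributes: upper rung; harmful: lower). Attributes
missing from a profile score 0 and are logged, mirroring the exclusion
of unmeasured attributes rather than erroring. The additives domain is
present but scores from zero-valued synthetic data. Consequently
absolute FCS values are not reproducible here - the published
per-scenario scores are covered as a verbatim, checksum-verified fixture
(`table1_scores()`), and all published-statistics tests run against that
fixture.

## What the synthetic generator emulates - and what it does not

`generate_foods()` draws one representative food per group with
lognormal-jittered nutrient densities around realistic group baselines
(lognormal for positivity), calorie densities in +/-15% bands around
realistic values, and impact factors for all 18 indicators built from a
per-gram global-warming baseline with indicator-specific scales. Two
structural features of the real data are reproduced deliberately:

* animal meats cost strictly more global warming per gram than legumes
  (enforced ratio), so meat-to-legume substitution lowers
  climate-linked indicators along every ladder;
* water use and freshwater eutrophication follow an irrigation-weighted,
  plant-heavy pattern instead of the global-warming gradient, so they
  decorrelate from the other 16 indicators - the same two indicators the
  source analysis singles out as uncorrelated.

Plant groups are denser in fiber, folate, vitamins C/K and potassium;
animal groups in B12, vitamin D, zinc and cholesterol; meat-heavy diets
are more calorie-dense, which is what drives per-100-kcal HENI upward
along the substitution ladder. The generator does *not* emulate intake
units per serving, cooking and storage losses, bioavailability, nutrient
correlations within a group, or the absolute published score levels:
passing tests demonstrate that the pipeline's structure and statistics
behave correctly under the assumed data-generating structure, not that
the synthetic world reproduces measured American diets.

The S1 -> S2 step pins fruits, vegetables, whole grains and fish to the
feasible anchor, so environmental impacts *rise* before the substitution
ladder brings them down - the monotonicity properties are therefore
asserted over S2-S9, the ladder proper, matching the initial impact
increase the source analysis reports for the S2 scenarios.

## Numerical choices and degenerate inputs

* Shares are stored as fractions; all I/O accepts percent with an
  explicit header flag. Validation requires shares >= 0 and a sum of 1
  within 1e-9; group masses reconstruct the total to 1e-6 g; CSV
  round-trips preserve shares to 1e-12 (17 significant digits written).
* Every domain error carries a stable condition class
  (`SUM_NOT_ONE`, `MASS_IMBALANCE`, `ZERO_ENERGY_DIET`,
  `MISSING_FACTOR`, `SCHEDULE_INCOMPLETE`, ...), so callers can
  dispatch rather than parse messages.
* Zero-energy diets, zero RACC masses, zero baselines and empty subsets
  are rejected, not silently propagated; singleton subsets return an
  `NA` SD with a warning.
* Threshold counts use strict inequality (a score of exactly 71 does
  not count as "above 71").
* Kruskal-Wallis H is computed from explicit rank sums with the
  standard tie correction and cross-checked against the reference
  implementation in the test suite; ranks expose tie-averaged values
  whose sum is always N(N+1)/2.
* The FCS rescale applies no clamping; out-of-range raw scores produce
  out-of-range scaled scores with a classed warning, never silent
  truncation.

## Problem sizes

All computations are desk-scale by design: 24 scenarios x 14 groups,
46 attributes, 18 indicators, 15 risks. The full test suite (about 700
assertions, including property loops over seeded random compositions
and an end-to-end pipeline run) completes in well under a minute; the
published-table statistics recompute in milliseconds from the packaged
fixtures.

## Known limitations

* Absolute FCS and HENI levels depend on external inputs (authoritative
  cut-points, a nutrient-analysis service) that are not packaged;
  only the published score table itself, as a fixture, carries them.
* The published 54.72% and 46.22% global-warming reductions depend on
  the study's supplementary per-food factor workbooks; without them the
  package demonstrates the same substitution machinery on synthetic
  factor tables and labels those results synthetic.
* Uncertainty is not propagated: the impact model consumes means only.
* Whether published percent reductions were computed per day or per
  100 kcal is not documented; both bases are always emitted, and the
  reductions differ between bases whenever scenario calories differ.
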