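Package: dietshift
Title: Nutrition-Environment Trade-Off Modelling of Meat-to-Legume Diet
    Substitution Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models composite daily diets (14 food groups, fixed 1.8 kg
    total mass) transitioning from a current American-style diet toward an
    optimal plant-forward diet by partial meat-to-legume substitution under
    three consumption models. Scores each scenario's nutritional quality
    with the Health Nutritional Index (HENI, healthy-life minutes per 100
    kcal from Global Burden of Disease dietary-risk factors) and an adapted
    Food Compass Score (46 attributes in 7 domains, rescaled to 1-100), and
    its environmental footprint across 18 life-cycle midpoint indicators
    using RACC-normalized per-food impact factors. Includes the trade-off
    statistics layer (Pearson correlations, subgroup summaries,
    Kruskal-Wallis ranking, Pareto flagging) and a seeded synthetic-data
    generator so the whole pipeline is testable without external services.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
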