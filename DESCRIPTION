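Package: frbudget
Title: Food Reference Budgets for Healthy Diets via Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes Food Reference Budgets: the minimum monetary amount
    needed to purchase a food basket that is both healthy and close to a
    population's observed consumption habits. An observed national diet is
    scaled to the recommended energy intake, transformed by a goal-programming
    linear programme into the closest diet satisfying nutrient and food-based
    recommendations (minimising the total departure of mean food intake), and
    priced at lower price percentiles of retail price observations, with
    cross-country price transfer through price level indices and affordability
    expressed as a share of median equivalised net income.  Includes a
    synthetic-data generator emulating household-budget-survey style inputs,
    a stepwise floor-relaxation loop for infeasible diets, and descriptive
    analytics comparing observed and optimised diets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    boot,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
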