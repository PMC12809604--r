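# frbudget

Food Reference Budgets — the minimum monetary amount needed to purchase a
food basket that is both **healthy** and **socially acceptable** — computed
by linear programming from observed national diets, nutrient recommendations
and retail price data.

The package is aimed at public-health economists and nutrition researchers
who want to quantify the cost of a healthy diet per country and compare it
with incomes or social-benefit allowances, without hand-designed expert
baskets: the optimised basket stays as close as possible to what the
population actually eats.

## The model

For a country with observed mean at-home consumption `C_i` (g/person/day)
over `n` food groups, the diet is first anchored to the recommended energy
intake `rE` of a reference person (man: 82 kg, PAL 1.4, 9.4 MJ/day; woman:
66 kg, PAL 1.4, 7.55 MJ/day) by a single proportional factor that preserves
the percentage energy structure between groups:

    sC_i = C_i * rE / cE        (cE = observed energy of the diet)

The optimised quantities `X_i` minimise the **total departure of mean food
intake**,

    TDMI = sum_i |X_i - sC_i| / sC_i

subject to recommendation bounds (a goal-programming objective; the absolute
values are linearised with paired deviation variables `X_i = sC_i (1 + p_i -
q_i)`, minimising `sum(p_i + q_i)`). The bounds are nutrient reference
values and food-based rules, each converted from its native unit into
gram-space:

* `%energy` via the EC 90/496/EEC energy factors (e.g. free sugars
  < 10 %E → 55.3 g/day for the reference man),
* `g/kg bodyweight` via the person's weight,
* `mg/MJ` via the recommended energy intake,
* fruit + vegetables supplying 7–14 % of energy at a mean caloric density of
  32 kcal/100 g (→ lower bound ≈ 491 g/day for a man),
* total water (from food and beverages) at the recommendation with a +30 %
  cap,
* caffeine as a mass cap on coffee + tea (4 cups of 200 g, scaled by body
  weight for the woman),
* a vitamin D floor of 5 µg/day.

Every consumed group must retain at least 10 % of its scaled observed
quantity; when that makes the model infeasible the floor is lowered in 1 %
steps until it solves.

Optimised baskets are priced at lower percentiles (20th–50th) of per-group
retail price observations, transferred to other countries through price
level indices, and expressed as €/day and as a share of median equivalised
net income.

The licensed survey inputs (household budget surveys, food composition
databases, CPI micro-prices) are not distributable, so the package ships a
synthetic-data generator that emulates their statistical shape; all analyses
run end-to-end on it.

## Worked example

```r
library(frbudget)

bundle <- synth_generate(synth_config(n_countries = 3, seed = 42))
run <- frb_run(bundle, allowance = 4.75)
run
#> Food Reference Budget run
#>   diets solved: 6 of 6
#>   budget rows: 16 (percentiles 20/30/40/50)
#>   cost range at 20th percentile: 1.87 - 4.19 EUR/day
```

Six diets: 3 countries × 2 reference persons. One country is generated
without price level indices (as happens with real index coverage), so 2
countries × 2 persons × 4 percentiles = 16 budget rows. A single fit:

```r
fit <- run$fits[["S02.man"]]
fit
#> Optimised healthy diet: S02 (man)
#>   food groups: 60   consumption floor: 10 %
#>   total departure of mean food intake (TDMI): 3.3697
#>   binding constraints: 6
```

The optimised diet for this synthetic country departs from the scaled
observed diet by a summed relative deviation of 3.37; six recommendation
bounds are binding at the optimum. `summary(fit)` breaks the change into
the ten analysis categories (the largest increases here are eggs +84 % and
carbohydrate-rich foods +9 %), and the budget table prices each solved
basket:

```r
subset(run$budgets, percentile == 20)
#>    country gender percentile cost_eur_day annual_cost_eur income_share_pct
#> 1      S02    man         20     1.931044        704.8311         6.624457
#> 5      S03    man         20     4.186680       1528.1383         4.432984
#> 9      S02  woman         20     1.866491        681.2692         6.403007
#> 13     S03  woman         20     4.016668       1466.0840         4.252970
```

`cost_eur_day` is the basket cost at the 20th price percentile after PLI
transfer; `income_share_pct` relates the annualised cost to the country's
median equivalised net income. `run$benchmark` reports, per person, the
highest percentile still affordable under the €4.75/day allowance.

`plot(fit)` draws the observed-versus-optimised scatter with the angle
bisector: groups above the line must increase to meet the recommendations.

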