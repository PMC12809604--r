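---
title: "Food Reference Budgets by linear programming: model and design notes"
author: "frbudget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food Reference Budgets by linear programming: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frbudget)
```

## The problem

A Food Reference Budget is the minimum amount of money a person needs to buy
a diet that is healthy *and* close to what their population actually eats.
Expert-designed baskets are criticised as normative; baskets derived from
low-income spending risk circularity (constrained budgets produce constrained
diets). The approach implemented here is survey-led: start from the observed
mean diet of a country, change it as little as possible until it satisfies
every nutrient and food-based recommendation, then price the result.

## Model

### Energy scaling

Observed mean energy intakes deviate from recommended intakes, so the
observed diet is first rescaled by the single factor $rE/cE$, where $cE$ is
the energy of the observed diet and $rE$ the reference person's recommended
intake. This preserves the percentage energy structure between food groups —
the country's dietary "signature" — while anchoring total energy. The factor
is applied to *every* group, including zero- and low-energy beverages: the
proportional rule is applied literally, because any exemption scheme would
need information the aggregate data does not carry.

### Objective

With scaled consumption $sC_i > 0$ and optimised quantities $X_i$, the model
minimises the total departure of mean food intake

$$\mathrm{TDMI} = \sum_{i=1}^{n} \frac{|X_i - sC_i|}{sC_i},$$

the classic goal-programming diet objective. Standardising by $sC_i$ makes a
10 g change in a 20 g/day group as costly as a 100 g change in a 200 g/day
group, so small habitual foods are not sacrificed first.

The absolute values are linearised with paired nonnegative deviation
variables: $X_i = sC_i\,(1 + p_i - q_i)$, minimise $\sum_i (p_i + q_i)$. At
any optimum $p_i$ and $q_i$ cannot both be positive (each carries positive
cost and they cancel in $X_i$), so the optimal objective equals TDMI. The
model object carries all $3n$ variables $(X, p, q)$; the solver eliminates
the $n$ identity rows by substitution before pivoting (see *Numerical
choices*).

### Constraints

Recommendations arrive in heterogeneous native units and are converted once,
at assembly time, into linear bounds over food-group grams:

| rule | conversion | default |
|---|---|---|
| nutrient, `g/mg/µg per day` | per-gram nutrient contents as coefficients | e.g. fibre ≥ 25 g |
| `%energy` | $(v/100 \cdot rE_{kJ}) / f$ with energy factor $f$ (kJ/g) | free sugars < 10 %E |
| `g/kg bodyweight` | $v \times$ body weight | protein ≥ 0.83 g/kg |
| `mg/MJ` | $v \times rE_{MJ}$ | thiamin ≥ 0.1 mg/MJ |
| fruit + veg energy share | mass bound at 32 kcal/100 g mean density | 7–14 %E |
| water | all-groups water coefficients; cap at 1.3 × recommendation | 2.5/2.0 kg + 30 % |
| caffeine | mass cap on coffee + tea, 4 × 200 g cups, body-weight scaled | 800 g (man) |
| vitamin D | plain floor (endogenous synthesis covers the rest) | ≥ 5 µg |

The energy factors are fixed to the EC 90/496/EEC labelling values (protein
and carbohydrate 17 kJ/g, fat 37, fibre 8, alcohol 29) and exposed in the
constraint configuration. The reference persons are a 25–49-year-old man
(82 kg, PAL 1.4, 9.4 MJ/day) and woman (66 kg, PAL 1.4, 7.55 MJ/day);
1 kcal = 4.184 kJ exactly, converted once.

The shipped default constraint set is deliberately labelled *illustrative*:
it has the structure and style of the EFSA dietary reference values for this
age band, but the licensed reference tables are not bundled, and a user
aiming at a faithful national application must supply their own set via the
YAML constraint format. The structural rules above carry their standard
published values.

Two decisions here were genuinely open:

* **No explicit energy row.** Energy anchoring happens in the scaling step,
  and all %-energy rules are converted with the *fixed* $rE$ rather than the
  model's own energy, so the LP never needs an energy constraint; the
  macronutrient range bounds (fat 20–35 %E, carbohydrate 45–60 %E) keep
  optimised diets near $rE$ implicitly. This keeps the constraint-unit
  vocabulary closed and the conversions transparent.
* **Caffeine scaling for the woman** uses the mass ratio 66/82 of the body
  weights. A caffeine-per-kg rule would give the same form with a different
  anchor; the mass-ratio reading is implemented and flagged here.

### Consumption floors and relaxation

Social acceptability is enforced by floors: every consumed group must keep
at least 10 % of its scaled observed quantity, so no food the population
eats disappears from the basket. Floors apply to $sC$ (the model's reference
vector), not the unscaled diet — the two differ only by the scalar energy
factor, and $sC$ is the quantity the objective is standardised by.

Unhealthy observed diets can make the constraint system infeasible at 10 %.
The standard handling is implemented as a loop: lower the floor in 1 % steps
until the model solves, recording every attempt. A model infeasible even at
the configured minimum floor returns an infeasibility certificate with the
full trace.

Groups with *no* consumption record are treated as absent, not zero: they
drop out of the model dimension entirely (the relative departure is
undefined at $sC_i = 0$ and a floor cannot apply), which is also how a
survey gap in one country's data is handled — that country simply runs on
fewer groups.

### Pricing and affordability

Basket costing uses lower percentiles (20th–50th) of the per-group price
observation sets rather than means, reflecting that a price-conscious
shopper does not pay the average price. The percentile estimator is the
linear-interpolation order-statistic quantile (`stats::quantile` type 7, the
convention whose 50th percentile is the sample median); the convention is
config-overridable since price percentiles are not standardised across
statistical offices. Percentiles are computed on the pooled observations of
each group.

Prices exist for one base country only; other countries' prices are derived
as $p \cdot \mathrm{PLI}_t / \mathrm{PLI}_b$ from relative price level
indices, applied to the percentile prices (per-country observation sets do
not exist in this design). Countries without indices are skipped in the
budget stage with a warning — their optimised diets are still computed.
Affordability is the annualised cost (365 days) over the median equivalised
net income, as a percentage; an optional daily allowance is benchmarked by
returning the highest percentile whose cost stays within it.

## The synthetic data generator

The real inputs — household budget survey consumption, a national food
composition database, CPI micro-prices, Eurostat price level indices and
incomes — are licensed and cannot ship. The generator emulates their
statistical shape so the full pipeline runs and can be tested end-to-end:

* **Registry**: a 62-group, ECOICOP-style commodity classification with the
  two standard exclusions (alcoholic beverages, baby food), leaving 60
  modelling groups. The codes are realistic but synthetic.
* **Consumption**: each country×person diet starts from a Dirichlet draw
  over *energy* shares (matching the model's energy-structure framing),
  converted to grams via the groups' energy densities; near-zero-energy
  beverages get volumes directly, scaled with energy needs. The draw is then
  projected onto the recommendation polytope by an auxiliary LP with energy
  pinned at $rE$, which guarantees by construction that an
  `unhealthiness = 0` bundle is feasible at the 10 % floor with zero
  departure. The configured unhealthiness (default 0.3) then shifts mass
  from fruit, vegetables and fish towards sweets and fats, and the total is
  moved to the country's observed energy level (mean 1.08 × $rE$, lognormal
  spread 0.08 — observed intakes tend to exceed recommendations).
* **Nutrients**: category archetypes with ±15 % per-group jitter; energy is
  computed *exactly* from the energy factors and water is truncated so water
  + macronutrient mass never exceeds 100 g/100 g — the table is internally
  consistent by construction.
* **Prices**: lognormal observations per group (≥ 30, default 40) around
  category-level base prices, giving the right-skew of retail prices; the
  lognormal median equals the base price. Coffee and tea are priced on a
  prepared-beverage basis to stay consistent with their consumption
  quantities — a simplification of how beverage purchases are actually
  recorded.
* **Incomes and PLIs**: incomes are log-spaced across 3 284–34 472 €/year
  with exact endpoints; each country's overall price level rises with its
  income (wealthier countries are more expensive), with per-group jitter.
  One country is generated without indices by default, to exercise the
  missing-index path.

What the generator does **not** emulate: real cross-country preference
correlations, survey weighting and household composition, seasonal and
regional price structure, or any specific country's diet. Passing tests
therefore demonstrate the correctness and invariances of the machinery —
unit conversions, LP optimality, floor relaxation, pricing arithmetic — not
the empirical magnitudes a licensed-data application would produce.

`make_infeasible_case()` constructs relaxation test material: it calibrates
a mass cap on the sweets groups against the scaled diet so the model is
infeasible above a target floor and solvable exactly at it, and verifies the
certificate at generation time by solving at every floor on the way down.

## Numerical choices

* **Solver**: a deterministic dense two-phase simplex (`boot::simplex`),
  single evaluation path, so repeated solves are bit-identical and LP
  degeneracy cannot produce run-to-run alternative optima. As a presolve
  step the $n$ identity rows $X_i = sC_i(1+p_i-q_i)$ are eliminated by
  substitution: the simplex works on the $2n$ deviation variables, floors
  reduce to simple caps $q_i \le 1 - \mathrm{floor}$, and no equality
  artificials are needed — removing the degeneracy that a dense phase 1
  handles poorly. The solution is checked after the fact: the reported
  objective must agree with the directly recomputed TDMI within $10^{-6}$.
* **Binding constraints** are reported at an absolute slack tolerance of
  $10^{-7}$ (a reporting aid, exposed as a parameter).
* **Unit conversions happen exactly once**, at read/assembly time; all
  internal quantities are g/person/day, all prices €/kg, energy in kcal with
  the single constant 4.184 kJ/kcal.
* **Annualisation** uses 365 days.
* Degenerate inputs fail loudly and early: zero-energy diets, nonpositive
  prices or incomes or indices, unknown codes, unconvertible units and
  empty group sets are all hard errors naming the offender.

## Problem sizes

The test suite cross-checks the LP against an exhaustive 1 g-grid search on
dozens of 4–6-group instances (where enumeration is tractable) and runs the
pipeline properties on 12–20-group, 1–3-country bundles; the acceptance
script runs the full default study of 26 countries × 2 persons × 60 groups,
which solves in a few seconds. These sizes were chosen so the independent
oracles stay exact and the whole suite runs quickly on one CPU.

## Known limitations

* The default constraint set is illustrative, not a reproduction of any
  official reference-value table; faithful applications must supply their
  own.
* Aggregate mean consumption hides within-country variation: floors are
  fractions of the mean, and no upper consumption limits are imposed (the
  water cap and the caffeine cap act as de-facto upper limits on beverages).
* The commodity-level classification cannot distinguish wholegrain from
  refined products, or home consumption from out-of-home eating.
* One objective norm (L1, relative) is implemented; L2 or max-deviation
  variants are extensions, not options.
* Budgets are point estimates at fixed percentiles; no inference is
  attached to them.
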