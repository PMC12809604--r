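#' Configuration for the synthetic data generator
#'
#' The generator emulates the statistical shape of the licensed survey inputs
#' the pipeline is designed for: per-country mean at-home diets over ~60
#' commodity groups, a per-group nutrient composition table, right-skewed
#' retail price observation sets for one base country, country price level
#' indices, and median equivalised net incomes.
#'
#' @param seed integer RNG seed; the whole bundle is a pure function of the
#'   config.
#' @param n_countries number of countries (default 26).
#' @param n_groups number of food groups drawn from the default registry
#'   (default 60, the full registry); must be at least the number of analysis
#'   categories.
#' @param unhealthiness in [0, 1]: how far observed diets sit from the
#'   recommendations (mass shifted from fruit, vegetables and fish towards
#'   sweets, snacks and fats).  0 produces diets that already satisfy every
#'   bound after energy scaling.
#' @param energy_mean mean ratio of observed to recommended energy intake
#'   (observed intakes tend to exceed recommendations).
#' @param energy_sd lognormal spread of that ratio across countries.
#' @param price_sdlog lognormal sigma of within-group price observations.
#' @param n_price_obs observations per group (>= 30).
#' @param income_range EUR/year span of median equivalised net incomes; the
#'   endpoints are hit exactly, interior countries are log-spaced.
#' @param pli_spread per-group jitter (lognormal sigma) around each country's
#'   overall price level.
#' @param pli_holdout number of countries (excluding the base country)
#'   generated without price level indices, to exercise the missing-index
#'   path (default 1).
#' @param dirichlet_concentration concentration of the Dirichlet draw over
#'   energy shares; higher = countries more alike.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1, n_countries = 26, n_groups = 60,
                         unhealthiness = 0.3, energy_mean = 1.08,
                         energy_sd = 0.08, price_sdlog = 0.35,
                         n_price_obs = 40,
                         income_range = c(3284, 34472),
                         pli_spread = 0.05, pli_holdout = 1,
                         dirichlet_concentration = 60) {
  if (unhealthiness < 0 || unhealthiness > 1)
    stop("unhealthiness must be in [0, 1]")
  if (n_groups < length(food_categories()))
    stop("n_groups must be at least the number of analysis categories (",
         length(food_categories()), ")")
  if (energy_sd < 0 || price_sdlog < 0 || pli_spread < 0)
    stop("spreads must be nonnegative")
  if (n_price_obs < 1) stop("need at least one price observation per group")
  structure(list(seed = seed, n_countries = n_countries, n_groups = n_groups,
                 unhealthiness = unhealthiness, energy_mean = energy_mean,
                 energy_sd = energy_sd, price_sdlog = price_sdlog,
                 n_price_obs = n_price_obs, income_range = income_range,
                 pli_spread = pli_spread, pli_holdout = pli_holdout,
                 dirichlet_concentration = dirichlet_concentration),
            class = "synth_config")
}

# Category archetypes: nutrient contents per 100 g before per-group jitter.
# Energy is NOT listed; it is computed exactly from the energy factors so the
# composition table is internally consistent by construction.
category_archetypes <- function() {
  a <- function(protein, fat, sat_frac, pufa_frac, cholesterol, carbohydrate,
                free_sugars, fibre, water, salt, thiamin, vitamin_c,
                vitamin_d, calcium, iron)
    c(protein = protein, fat = fat, sat_frac = sat_frac,
      pufa_frac = pufa_frac, cholesterol = cholesterol,
      carbohydrate = carbohydrate, free_sugars = free_sugars, fibre = fibre,
      water = water, salt = salt, thiamin = thiamin, vitamin_c = vitamin_c,
      vitamin_d = vitamin_d, calcium = calcium, iron = iron)
  list(
    "foods rich in carbohydrates" = a(8, 2, .25, .3, 0, 50, 2, 5, 33, 1,
                                      .2, 0, 0, 30, 2),
    "fruits" = a(.8, .3, .2, .3, 0, 12, 1, 2.5, 83, 0, .04, 40, 0, 15, .4),
    "vegetables" = a(2.2, .3, .2, .3, 0, 4, .3, 2.8, 89, .05, .08, 30, 0,
                     45, 1.5),
    "meat" = a(20, 10, .4, .1, 60, .5, 0, 0, 67, .8, .4, 0, .5, 10, 2.3),
    "fish" = a(18, 8, .25, .35, 55, 0, 0, 0, 71, .7, .08, 0, 8, 20, .8),
    "milk and dairy products" = a(6, 4.5, .62, .05, 14, 5, 1, 0, 82, .3,
                                  .04, 1, .5, 250, .1),
    "eggs" = a(12.5, 10, .3, .15, 400, 1, 0, 0, 75, .35, .1, 0, 2.9, 55, 1.8),
    "oils and fats" = a(.2, 85, .3, .3, 40, .2, 0, 0, 12, .4, 0, 0, 2, 5, 0),
    "sweets and snacks" = a(4, 18, .5, .1, 10, 62, 45, 2, 10, .4, .03, 0,
                            0, 40, 1.5),
    "others" = a(4, 8, .3, .2, 10, 12, 3, 1.5, 70, 1.8, .05, 3, .2, 30, 1.2))
}

# Beverage overrides keyed by registry tag or code (prepared-beverage basis).
beverage_archetypes <- function() {
  a <- category_archetypes()[[1]]  # reuse field order
  z <- a * 0
  mk <- function(...) { v <- z; args <- list(...); v[names(args)] <- unlist(args); v }
  list(
    coffee = mk(protein = .2, carbohydrate = .3, water = 99, calcium = 4),
    tea = mk(carbohydrate = .1, water = 99.5, calcium = 1),
    water = mk(water = 99.9, calcium = 10),
    "01.2.2.2" = mk(carbohydrate = 9, free_sugars = 9, water = 90),
    "01.2.2.3" = mk(protein = .5, carbohydrate = 10, free_sugars = 9,
                    water = 88, vitamin_c = 30, calcium = 10),
    "01.2.1.3" = mk(protein = 8, fat = 20, sat_frac = .6, carbohydrate = 50,
                    free_sugars = 40, fibre = 8, water = 3, calcium = 150,
                    iron = 8))
}

# Healthy-ish baseline energy shares per category (energy-bearing food only;
# low-energy beverages get grams directly).
base_energy_shares <- function() {
  c("foods rich in carbohydrates" = .40, "fruits" = .07, "vegetables" = .05,
    "meat" = .12, "fish" = .035, "milk and dairy products" = .12,
    "eggs" = .02, "oils and fats" = .08, "sweets and snacks" = .06,
    "others" = .045)
}

# grams assigned directly to near-zero-energy beverage groups
beverage_grams <- function() {
  c(coffee = 400, tea = 200, water = 1100, "01.2.2.2" = 250, "01.2.2.3" = 150)
}

synth_registry <- function(n_groups) {
  reg <- default_registry()
  if (n_groups > nrow(reg))
    stop("n_groups exceeds the registry size (", nrow(reg), ")")
  if (n_groups == nrow(reg)) return(reg)
  # keep the rule-relevant beverage groups (coffee also covers the "others"
  # category), then one group per uncovered category, then fill in code order
  keep <- reg$code[reg$tag == "coffee"]
  for (ct in setdiff(food_categories(),
                     reg$category[reg$code %in% keep]))
    keep <- c(keep, reg$code[reg$category == ct][1])
  for (tg in c("tea", "water"))
    if (length(keep) < n_groups)
      keep <- unique(c(keep, reg$code[reg$tag == tg]))
  extra <- setdiff(reg$code, keep)
  keep <- c(keep, extra[seq_len(max(0, n_groups - length(keep)))])
  food_registry(as.data.frame(reg[reg$code %in% keep, ]),
                exclude = character())
}

synth_nutrients <- function(registry) {
  arch <- category_archetypes()
  bev <- beverage_archetypes()
  keys <- c("protein", "fat", "satfat", "pufa", "cholesterol", "carbohydrate",
            "free_sugars", "fibre", "water", "salt", "thiamin", "vitamin_c",
            "vitamin_d", "calcium", "iron")
  n <- nrow(registry)
  mat <- matrix(0, n, length(keys) + 1,
                dimnames = list(registry$code, c("energy", keys)))
  fk <- energy_factors_kj()
  for (i in seq_len(n)) {
    base <- if (registry$tag[i] %in% names(bev)) bev[[registry$tag[i]]]
            else if (registry$code[i] %in% names(bev)) bev[[registry$code[i]]]
            else arch[[registry$category[i]]]
    jit <- stats::runif(length(base), 0.85, 1.15)
    v <- base * jit
    # keep mass balance: scale macros down if they would exceed 100 g
    macro <- v[["protein"]] + v[["fat"]] + v[["carbohydrate"]] +
      v[["fibre"]] + v[["salt"]]
    if (macro + v[["water"]] > 100)
      v[["water"]] <- max(0, 100 - macro)
    v[["free_sugars"]] <- min(v[["free_sugars"]], v[["carbohydrate"]])
    mat[i, "protein"] <- v[["protein"]]
    mat[i, "fat"] <- v[["fat"]]
    mat[i, "satfat"] <- v[["fat"]] * min(1, v[["sat_frac"]])
    mat[i, "pufa"] <- v[["fat"]] * min(1, v[["pufa_frac"]])
    mat[i, "cholesterol"] <- v[["cholesterol"]]
    mat[i, "carbohydrate"] <- v[["carbohydrate"]]
    mat[i, "free_sugars"] <- v[["free_sugars"]]
    mat[i, "fibre"] <- v[["fibre"]]
    mat[i, "water"] <- v[["water"]]
    mat[i, "salt"] <- v[["salt"]]
    mat[i, "thiamin"] <- v[["thiamin"]]
    mat[i, "vitamin_c"] <- v[["vitamin_c"]]
    mat[i, "vitamin_d"] <- v[["vitamin_d"]]
    mat[i, "calcium"] <- v[["calcium"]]
    mat[i, "iron"] <- v[["iron"]]
    mat[i, "energy"] <- (17 * (mat[i, "protein"] + mat[i, "carbohydrate"]) +
                           37 * mat[i, "fat"] + 8 * mat[i, "fibre"]) /
      KJ_PER_KCAL
  }
  nutrient_table(mat)
}

# one raw diet (g/day) at energy ~ rE: Dirichlet energy shares over
# energy-bearing groups + fixed-ish grams for low-energy beverages
synth_raw_diet <- function(registry, nutrients, person, conc) {
  dens <- nutrients[registry$code, "energy"] / 100   # kcal per g
  bevg <- beverage_grams()
  direct <- stats::setNames(numeric(0), character(0))
  for (i in seq_len(nrow(registry))) {
    key <- if (registry$tag[i] %in% names(bevg)) registry$tag[i]
           else if (registry$code[i] %in% names(bevg)) registry$code[i]
           else NA
    if (!is.na(key))  # beverage volumes scale with energy needs
      direct[registry$code[i]] <- bevg[[key]] * (person$energy_mj / 9.4) *
        stats::runif(1, 0.75, 1.25)
  }
  en_codes <- setdiff(registry$code, names(direct))
  shares_cat <- base_energy_shares()
  alpha <- vapply(en_codes, function(code) {
    ct <- registry$category[registry$code == code]
    shares_cat[[ct]] / sum(registry$category[registry$code %in% en_codes] == ct)
  }, numeric(1))
  g <- stats::rgamma(length(alpha), shape = alpha * conc, rate = 1)
  shares <- g / sum(g)
  bev_energy <- sum(direct * dens[names(direct)])
  target <- max(person$energy_kcal - bev_energy, 0.5 * person$energy_kcal)
  grams <- shares * target / dens[en_codes]
  c(grams, direct)[registry$code]
}

# shift mass away from fruit/veg/fish towards sweets/oils, strength u
distort_diet <- function(H, registry, u) {
  if (u <= 0) return(H)
  idx <- match(names(H), registry$code)
  cats <- registry$category[idx]
  from <- cats %in% c("fruits", "vegetables", "fish")
  to <- cats %in% c("sweets and snacks", "oils and fats")
  moved <- 0.6 * u * H[from]
  out <- H
  out[from] <- H[from] - moved
  out[to] <- H[to] * (1 + sum(moved) * 0.8 / sum(H[to]))
  out
}

#' Generate a complete synthetic dataset bundle
#'
#' Produces every input the pipeline needs, internally consistent and
#' reproducible from the seed.  Observed diets are built in three steps:
#' a Dirichlet draw over energy shares gives each country an individual raw
#' diet at roughly the recommended energy; that diet is projected onto the
#' recommendation polytope by an auxiliary LP run, guaranteeing that a fully
#' "healthy" bundle (unhealthiness 0) is feasible at the 10 \% floor with
#' zero departure; the configured unhealthiness then shifts mass from fruit,
#' vegetables and fish towards sweets and fats, and the total is moved to the
#' country's observed energy level.
#'
#' @param config a \code{synth_config}.
#' @return A bundle list: \code{registry}, \code{nutrients},
#'   \code{profiles} (consumption profiles per country x gender),
#'   \code{prices}, \code{pli}, \code{incomes}, \code{base_country},
#'   \code{pli_missing}, \code{constraints}, \code{config}.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  registry <- synth_registry(config$n_groups)
  nutrients <- synth_nutrients(registry)
  constraints <- default_constraints()
  countries <- sprintf("S%02d", seq_len(config$n_countries))
  persons <- list(man = person_profile("man"),
                  woman = person_profile("woman"))
  profiles <- list()
  for (ctry in countries) {
    e_ratio <- config$energy_mean * exp(stats::rnorm(1, 0, config$energy_sd))
    for (g in names(persons)) {
      p <- persons[[g]]
      raw <- synth_raw_diet(registry, nutrients, p,
                            config$dirichlet_concentration)
      bounds <- assemble_constraints(constraints, registry, nutrients, p)
      # pin projected energy to rE so that energy scaling is the identity on
      # the projected diet: the healthy bundle is then feasible with zero
      # departure by construction
      e_coef <- stats::setNames(nutrients[registry$code, "energy"] / 100,
                                registry$code)
      proj_bounds <- c(bounds,
                       list(linear_bound("energy_pin", e_coef, "=",
                                         p$energy_kcal)))
      proj <- solve_diet_lp(linearize(raw, proj_bounds, floor = 0.10))
      if (proj$status != "optimal")
        stop("synthetic generation failed: recommendation set infeasible ",
             "for the raw diet of ", ctry, " (", g, ")")
      H <- proj$X
      D <- distort_diet(H, registry, config$unhealthiness)
      cE_target <- p$energy_kcal * e_ratio
      C <- D * cE_target / profile_energy(D, nutrients)
      profiles[[paste(ctry, g, sep = ".")]] <-
        consumption_profile(ctry, C, gender = g)
    }
  }
  # prices: lognormal per group around a category base price (EUR/kg)
  base_price <- c("foods rich in carbohydrates" = 1.8, "fruits" = 2.5,
                  "vegetables" = 2.2, "meat" = 7, "fish" = 10,
                  "milk and dairy products" = 3.5, "eggs" = 3,
                  "oils and fats" = 4.5, "sweets and snacks" = 6,
                  "others" = 3)
  bev_price <- c(coffee = 1.5, tea = 1.0, water = 0.5,
                 "01.2.2.2" = 1.2, "01.2.2.3" = 1.8)
  prices <- lapply(seq_len(nrow(registry)), function(i) {
    key <- if (registry$tag[i] %in% names(bev_price)) registry$tag[i]
           else if (registry$code[i] %in% names(bev_price)) registry$code[i]
           else NA
    b <- if (!is.na(key)) bev_price[[key]]
         else base_price[[registry$category[i]]] * stats::runif(1, 0.7, 1.4)
    stats::rlnorm(config$n_price_obs, log(b), config$price_sdlog)
  })
  names(prices) <- registry$code
  # incomes: log-spaced across the configured range, endpoints exact
  incomes <- stats::setNames(
    exp(seq(log(config$income_range[1]), log(config$income_range[2]),
            length.out = config$n_countries)), countries)
  base_country <- countries[config$n_countries]
  # PLIs: overall country price level rises with income, per-group jitter
  lvl <- 45 + 95 * (incomes - min(incomes)) / diff(range(incomes)) *
    exp(stats::rnorm(config$n_countries, 0, 0.03))
  pli_missing <- character()
  if (config$pli_holdout > 0 && config$n_countries > 1)
    pli_missing <- setdiff(countries, base_country)[seq_len(
      min(config$pli_holdout, config$n_countries - 1))]
  pli <- do.call(rbind, lapply(setdiff(countries, pli_missing), function(ctry)
    data.frame(country = ctry, code = registry$code,
               index = lvl[[ctry]] *
                 exp(stats::rnorm(nrow(registry), 0, config$pli_spread)),
               stringsAsFactors = FALSE)))
  list(registry = registry, nutrients = nutrients,
       profiles = unname(profiles), prices = prices, pli = pli,
       incomes = incomes, base_country = base_country,
       pli_missing = pli_missing, constraints = constraints, config = config)
}

#' Construct a bundle that needs floor relaxation
#'
#' Builds a single-country bundle whose diet model is infeasible at every
#' floor above \code{target_floor} and solvable exactly at it, by adding a
#' mass cap on the sweets-and-snacks groups calibrated against the scaled
#' diet.  The certificate is verified at generation time by solving the model
#' at each floor from 10 \% down to the target; construction is retried over
#' seeds a bounded number of times.
#'
#' @param target_floor the floor (fraction < 0.10) at which the model must
#'   become solvable; 0.10 returns a plain feasible bundle.
#' @param config base \code{synth_config} (n_countries forced to 1,
#'   unhealthiness 0).
#' @param max_tries construction retries.
#' @return The bundle (as \code{synth_generate}), whose \code{constraints}
#'   include the calibrated cap, plus \code{target_floor}.
#' @export
make_infeasible_case <- function(target_floor = 0.08,
                                 config = synth_config(), max_tries = 5) {
  if (target_floor > 0.10) stop("target_floor must be at most 0.10")
  cfg <- config
  cfg$n_countries <- 1
  cfg$unhealthiness <- 0
  cfg$pli_holdout <- 0
  for (try in seq_len(max_tries)) {
    bundle <- synth_generate(cfg)
    bundle$target_floor <- target_floor
    if (target_floor >= 0.10) return(bundle)
    person <- person_profile("man")
    prof <- Filter(function(p) p$gender == "man", bundle$profiles)[[1]]
    sC <- scale_to_energy(prof, bundle$nutrients, person)$quantities
    sweets <- bundle$registry$code[bundle$registry$category ==
                                     "sweets and snacks"]
    cap <- (target_floor + 0.004) * sum(sC[sweets])
    specs <- c(bundle$constraints,
               list(constraint_spec("sweets_mass_cap", "upper", cap, "g/day",
                                    codes = sweets, applies_to = "man")))
    class(specs) <- c("constraint_set", "list")
    bounds <- assemble_constraints(specs, bundle$registry, bundle$nutrients,
                                   person)
    floors <- seq(0.10, target_floor, by = -0.01)
    status <- vapply(floors, function(f)
      solve_diet_lp(linearize(sC, bounds, floor = f))$status, "")
    want <- c(rep("infeasible", length(floors) - 1), "optimal")
    if (identical(status, want)) {
      bundle$constraints <- specs
      return(bundle)
    }
    cfg$seed <- cfg$seed + 1000003L
  }
  stop("could not construct a relaxation case after ", max_tries, " tries")
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' @param bundle a bundle from \code{synth_generate}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_registry(bundle$registry, file.path(dir, "registry.yaml"))
  write_nutrients(bundle$nutrients, file.path(dir, "nutrients.csv"))
  write_consumption(bundle$profiles, file.path(dir, "consumption.csv"))
  pr <- data.frame(
    code = rep(names(bundle$prices), lengths(bundle$prices)),
    price_eur_per_kg = unlist(bundle$prices, use.names = FALSE))
  utils::write.csv(pr, file.path(dir, "prices.csv"), row.names = FALSE)
  utils::write.csv(bundle$pli, file.path(dir, "pli.csv"), row.names = FALSE)
  utils::write.csv(data.frame(country = names(bundle$incomes),
                              median_equiv_net_income_eur_year =
                                unname(bundle$incomes)),
                   file.path(dir, "incomes.csv"), row.names = FALSE)
  write_constraints(bundle$constraints, file.path(dir, "constraints.yaml"))
  invisible(dir)
}
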