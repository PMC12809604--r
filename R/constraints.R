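#' Units accepted by constraint specifications
#' @export
constraint_units <- function() {
  c("g/day", "mg/day", "ug/day", "%energy", "g/kg-bw", "mg/MJ",
    "multiplier-of-lower-bound")
}

#' Construct a constraint specification
#'
#' One recommendation awaiting conversion into gram-space.  The target is
#' either a nutrient key (a per-gram coefficient row over nutrient contents)
#' or a set of food-group codes (a mass rule summing member quantities).  Code
#' sets may be given directly (\code{codes}), by analysis category
#' (\code{categories}) or by registry tag (\code{tags}); they are resolved
#' against the registry at assembly time.
#'
#' @param id unique identifier.
#' @param bound \code{"lower"} or \code{"upper"}.
#' @param value nonnegative number in \code{unit}.
#' @param unit one of \code{constraint_units()}.
#' @param nutrient nutrient key (exclusive with the code-set arguments).
#' @param codes,categories,tags food-group selectors for food-based rules.
#' @param applies_to \code{"man"}, \code{"woman"} or \code{"both"}.
#' @param energy_density_kcal_per_100g for \code{\%energy} rules on food-mass
#'   targets: the mean caloric density used to convert energy to grams.
#' @param scale_by_bodyweight if TRUE, the converted RHS is multiplied by
#'   bodyweight / \code{ref_bodyweight_kg} (used for the caffeine-via-mass cap,
#'   whose safe level scales with body weight).
#' @param ref_bodyweight_kg reference weight for \code{scale_by_bodyweight}.
#' @param notes free text.
#' @return A \code{constraint_spec}.
#' @export
constraint_spec <- function(id, bound, value, unit,
                            nutrient = NULL, codes = NULL, categories = NULL,
                            tags = NULL, applies_to = "both",
                            energy_density_kcal_per_100g = NULL,
                            scale_by_bodyweight = FALSE,
                            ref_bodyweight_kg = 82, notes = "") {
  if (!unit %in% constraint_units())
    stop("unknown unit '", unit, "' in constraint ", id)
  if (!bound %in% c("lower", "upper")) stop("bound must be lower/upper: ", id)
  if (value < 0) stop("constraint value must be nonnegative: ", id)
  if (!applies_to %in% c("man", "woman", "both"))
    stop("applies_to must be man/woman/both: ", id)
  food_based <- !is.null(codes) || !is.null(categories) || !is.null(tags)
  if (is.null(nutrient) == !food_based)
    stop("constraint ", id, " must target exactly one of: a nutrient, a code set")
  structure(list(id = id, bound = bound, value = value, unit = unit,
                 nutrient = nutrient, codes = codes, categories = categories,
                 tags = tags, applies_to = applies_to,
                 energy_density_kcal_per_100g = energy_density_kcal_per_100g,
                 scale_by_bodyweight = scale_by_bodyweight,
                 ref_bodyweight_kg = ref_bodyweight_kg, notes = notes),
            class = "constraint_spec")
}

#' A linear bound over food-group grams
#'
#' The gram-space realisation of a recommendation: a per-gram coefficient
#' vector over the model's food groups, a direction, and a right-hand side in
#' the coefficients' natural unit.
#'
#' @param id identifier (inherited from the spec).
#' @param coef named numeric vector over food-group codes (per-gram).
#' @param dir \code{">="}, \code{"<="} or \code{"="}.
#' @param rhs finite nonnegative number.
#' @return A \code{linear_bound}.
#' @export
linear_bound <- function(id, coef, dir, rhs) {
  stopifnot(dir %in% c(">=", "<=", "="), is.finite(rhs))
  structure(list(id = id, coef = coef, dir = dir, rhs = rhs),
            class = "linear_bound")
}

#' Convert a \%-of-energy recommendation to grams per day
#'
#' Recommendations expressed as a percentage of energy intake are converted to
#' g/day using the person's recommended energy intake and the energy factor of
#' the target nutrient: RHS = (value/100 x rE in kJ) / factor in kJ/g.
#'
#' @param value percentage of energy.
#' @param nutrient nutrient key; must have an energy factor.
#' @param person a \code{person_profile}.
#' @param factors kJ/g energy factors (default \code{energy_factors_kj()}).
#' @return Grams per day.
#' @export
convert_percent_energy <- function(value, nutrient, person,
                                   factors = energy_factors_kj()) {
  if (!nutrient %in% names(factors))
    stop("no energy factor for nutrient '", nutrient, "'")
  (value / 100) * (person$energy_mj * 1000) / factors[[nutrient]]
}

#' Convert a g-per-kg-bodyweight recommendation to grams per day
#' @param value g per kg bodyweight.
#' @param person a \code{person_profile}.
#' @return Grams per day (value x body weight).
#' @export
convert_bodyweight <- function(value, person) {
  if (person$bodyweight_kg <= 0) stop("body weight must be positive")
  value * person$bodyweight_kg
}

#' Convert a mg-per-MJ recommendation to mg per day
#' @param value mg per MJ.
#' @param person a \code{person_profile}.
#' @return mg per day (value x rE in MJ).
#' @export
convert_per_megajoule <- function(value, person) {
  value * person$energy_mj
}

#' Mean caloric density of the fruit-and-vegetable portion mix
#'
#' The recommended mix is 2 portions of fruit and 3 of vegetables; with mean
#' caloric contents of 50 and 20 kcal per 100 g this gives a weighted mean
#' density used to convert the 7-14 \%-of-energy range into grams.
#'
#' @param fruit_portions,veg_portions portion counts.
#' @param fruit_kcal,veg_kcal kcal per 100 g.
#' @return kcal per 100 g (32 at the defaults).
#' @export
fruit_veg_density <- function(fruit_portions = 2, veg_portions = 3,
                              fruit_kcal = 50, veg_kcal = 20) {
  (fruit_portions * fruit_kcal + veg_portions * veg_kcal) /
    (fruit_portions + veg_portions)
}

#' Fruit-and-vegetable mass bounds from the 7-14 \% energy rule
#'
#' Fruits and vegetables should provide between 7 and 14 \% of energy intake;
#' at a mean caloric density of 32 kcal per 100 g this becomes a pair of mass
#' bounds on the summed quantity of all fruit and vegetable groups.
#'
#' @param person a \code{person_profile}.
#' @param registry a \code{food_registry}; the code set is taken from the
#'   \code{fruits} and \code{vegetables} categories.
#' @param lower_pct,upper_pct energy-share percentages.
#' @param density_kcal_per_100g mean caloric density.
#' @return List of two \code{linear_bound}s (lower, upper).
#' @export
build_fruit_veg_bounds <- function(person, registry, lower_pct = 7,
                                   upper_pct = 14,
                                   density_kcal_per_100g = fruit_veg_density()) {
  codes <- registry$code[registry$category %in% c("fruits", "vegetables")]
  if (!length(codes)) stop("registry contains no fruit or vegetable groups")
  dens_per_g <- density_kcal_per_100g / 100
  coef <- stats::setNames(rep(1, length(codes)), codes)
  lo <- (lower_pct / 100) * person$energy_kcal / dens_per_g
  hi <- (upper_pct / 100) * person$energy_kcal / dens_per_g
  list(linear_bound("fruit_veg_lower", coef, ">=", lo),
       linear_bound("fruit_veg_upper", coef, "<=", hi))
}

#' Water bounds: recommendation plus a +30 \% cap
#'
#' The water recommendation covers water from beverages and from food, so the
#' coefficient row is each group's water content per gram across all groups.
#' To stop beverages from being over-represented, an upper bound caps total
#' water at 30 \% above the recommended amount.
#'
#' @param recommended_g recommended water in g/day.
#' @param nutrients a \code{nutrient_table} with a \code{water} column.
#' @param cap multiplier for the upper bound (1.3 = +30 \%).
#' @return List of two \code{linear_bound}s (lower, upper).
#' @export
build_water_bounds <- function(recommended_g, nutrients, cap = 1.3) {
  if (!"water" %in% colnames(nutrients))
    stop("nutrient table has no water contents")
  coef <- stats::setNames(nutrients[, "water"] / 100, rownames(nutrients))
  list(linear_bound("water_lower", coef, ">=", recommended_g),
       linear_bound("water_upper", coef, "<=", cap * recommended_g))
}

#' Caffeine cap as a mass limit on coffee and tea
#'
#' Caffeine is not in the composition table, so the safe intake (400 mg/day,
#' just under 100 mg per 200 ml cup, hence 4 cups) is enforced as a mass cap
#' on the coffee and tea groups: 4 x 200 g for the reference man.  Because
#' safe caffeine intake scales with body weight, the cap for other persons is
#' scaled by bodyweight relative to the 82 kg reference.
#'
#' @param person a \code{person_profile}.
#' @param registry a \code{food_registry}; coffee/tea groups are found via
#'   their \code{tag}.
#' @param safe_mg_per_day safe caffeine intake.
#' @param mg_per_cup caffeine per cup.
#' @param cup_g mass of one prepared cup (200 ml = 200 g).
#' @param ref_bodyweight_kg weight at which the cap is unscaled.
#' @return A single upper \code{linear_bound} over the coffee+tea groups.
#' @export
build_caffeine_bounds <- function(person, registry, safe_mg_per_day = 400,
                                  mg_per_cup = 100, cup_g = 200,
                                  ref_bodyweight_kg = 82) {
  codes <- registry$code[registry$tag %in% c("coffee", "tea")]
  if (!length(codes)) stop("registry contains no coffee or tea groups")
  cups <- safe_mg_per_day / mg_per_cup
  rhs <- cups * cup_g * person$bodyweight_kg / ref_bodyweight_kg
  linear_bound("caffeine_upper",
               stats::setNames(rep(1, length(codes)), codes), "<=", rhs)
}

# Resolve a spec's food-group code set against the registry.
resolve_codes <- function(spec, registry) {
  codes <- character()
  if (!is.null(spec$codes)) codes <- c(codes, spec$codes)
  if (!is.null(spec$categories))
    codes <- c(codes, registry$code[registry$category %in% spec$categories])
  if (!is.null(spec$tags))
    codes <- c(codes, registry$code[registry$tag %in% spec$tags])
  codes <- unique(codes)
  unknown <- setdiff(codes, registry$code)
  if (length(unknown))
    stop("constraint ", spec$id, " references unknown code(s): ",
         paste(unknown, collapse = ", "))
  codes
}

#' Assemble linear bounds from constraint specifications
#'
#' Converts every recommendation from its native unit into a gram-space
#' \code{linear_bound}: \code{\%energy} via the energy factors (or, for
#' food-mass targets, via the rule's caloric density), \code{g/kg-bw} via the
#' person's body weight, \code{mg/MJ} via the recommended energy intake, and
#' \code{multiplier-of-lower-bound} by multiplying the RHS of the matching
#' lower bound with the same target (the water +30 \% cap).  Nutrient targets
#' get the per-gram nutrient contents as coefficients; food-mass targets get
#' unit coefficients over their member groups.
#'
#' @param specs list of \code{constraint_spec}s (a \code{constraint_set}).
#' @param registry a \code{food_registry}.
#' @param nutrients a \code{nutrient_table}.
#' @param person a \code{person_profile}; specs whose \code{applies_to}
#'   excludes this gender are skipped.
#' @param factors kJ/g energy factors.
#' @return List of \code{linear_bound}s.
#' @export
assemble_constraints <- function(specs, registry, nutrients, person,
                                 factors = energy_factors_kj()) {
  specs <- Filter(function(s) s$applies_to %in% c("both", person$gender), specs)
  # multiplier specs need the converted RHS of their partner lower bound
  convert_rhs <- function(spec) {
    v <- spec$value
    rhs <- switch(spec$unit,
      "g/day" = , "mg/day" = , "ug/day" = v,
      "%energy" = {
        if (!is.null(spec$nutrient))
          convert_percent_energy(v, spec$nutrient, person, factors)
        else {
          dens <- spec$energy_density_kcal_per_100g
          if (is.null(dens))
            stop("constraint ", spec$id,
                 ": %energy on a food-mass target needs energy_density_kcal_per_100g")
          (v / 100) * person$energy_kcal / (dens / 100)
        }
      },
      "g/kg-bw" = convert_bodyweight(v, person),
      "mg/MJ" = convert_per_megajoule(v, person),
      "multiplier-of-lower-bound" = {
        same_target <- Filter(function(s)
          s$bound == "lower" && s$unit != "multiplier-of-lower-bound" &&
            identical(s$nutrient, spec$nutrient) &&
            identical(s$codes, spec$codes) &&
            identical(s$categories, spec$categories) &&
            identical(s$tags, spec$tags), specs)
        if (!length(same_target))
          stop("constraint ", spec$id,
               ": no lower bound with the same target to multiply")
        v * convert_rhs(same_target[[1]])
      },
      stop("unconvertible unit '", spec$unit, "' in constraint ", spec$id))
    if (isTRUE(spec$scale_by_bodyweight))
      rhs <- rhs * person$bodyweight_kg / spec$ref_bodyweight_kg
    rhs
  }
  lapply(specs, function(spec) {
    if (!is.null(spec$nutrient)) {
      if (!spec$nutrient %in% colnames(nutrients))
        stop("unknown nutrient '", spec$nutrient, "' in constraint ", spec$id)
      # native-unit check: g/day etc. must match the nutrient's canonical unit
      units <- nutrient_units()
      if (spec$unit %in% c("g/day", "mg/day", "ug/day") &&
          spec$nutrient %in% names(units)) {
        want <- c("g/day" = "g", "mg/day" = "mg", "ug/day" = "ug")[spec$unit]
        if (units[[spec$nutrient]] != want)
          stop("constraint ", spec$id, ": unit ", spec$unit,
               " does not match canonical unit of ", spec$nutrient,
               " (", units[[spec$nutrient]], ")")
      }
      coef <- stats::setNames(nutrients[, spec$nutrient] / 100,
                              rownames(nutrients))
    } else {
      codes <- resolve_codes(spec, registry)
      if (!length(codes))
        stop("constraint ", spec$id, " resolves to an empty code set")
      coef <- stats::setNames(rep(1, length(codes)), codes)
    }
    linear_bound(spec$id, coef,
                 if (spec$bound == "lower") ">=" else "<=", convert_rhs(spec))
  })
}

#' Check a diet against a set of linear bounds
#'
#' Independent feasibility check by direct accumulation: for each bound the
#' coefficient row is dotted with the diet (groups absent from the diet
#' contribute nothing) and compared with the RHS.
#'
#' @param quantities named g/day vector.
#' @param bounds list of \code{linear_bound}s.
#' @param tol absolute slack tolerance.
#' @return Logical vector named by bound id; attribute \code{slack} holds the
#'   signed slack (positive = satisfied with room).
#' @export
check_bounds <- function(quantities, bounds, tol = 1e-7) {
  ok <- logical(length(bounds))
  slack <- numeric(length(bounds))
  ids <- vapply(bounds, `[[`, "", "id")
  for (k in seq_along(bounds)) {
    b <- bounds[[k]]
    common <- intersect(names(b$coef), names(quantities))
    lhs <- sum(b$coef[common] * quantities[common])
    slack[k] <- switch(b$dir, ">=" = lhs - b$rhs, "<=" = b$rhs - lhs,
                       "=" = -abs(lhs - b$rhs))
    ok[k] <- slack[k] >= -tol
  }
  names(ok) <- ids
  attr(ok, "slack") <- stats::setNames(slack, ids)
  ok
}

#' Default illustrative constraint set
#'
#' A complete, internally consistent recommendation set in the style of the
#' EFSA dietary reference values for 25-49-year-olds, used by the synthetic
#' pipeline and as a template for user-supplied sets.  The nutrient bounds are
#' illustrative (the licensed reference tables are not bundled); the
#' structural rules -- free sugars below 10 \% of energy, fruit and vegetables
#' supplying 7-14 \% of energy at 32 kcal/100 g, water recommendation with a
#' +30 \% cap, the 4-cup coffee/tea caffeine cap scaled by body weight, a
#' vitamin D floor of 5 ug/day (endogenous synthesis covers the rest) -- carry
#' their standard published values.
#'
#' @return A \code{constraint_set} (list of \code{constraint_spec}s).
#' @export
default_constraints <- function() {
  cs <- list(
    constraint_spec("protein_lower", "lower", 0.83, "g/kg-bw",
                    nutrient = "protein"),
    constraint_spec("fat_lower", "lower", 20, "%energy", nutrient = "fat"),
    constraint_spec("fat_upper", "upper", 35, "%energy", nutrient = "fat"),
    constraint_spec("satfat_upper", "upper", 10, "%energy",
                    nutrient = "satfat"),
    constraint_spec("pufa_lower", "lower", 4, "%energy", nutrient = "pufa"),
    constraint_spec("cholesterol_upper", "upper", 300, "mg/day",
                    nutrient = "cholesterol"),
    constraint_spec("carbohydrate_lower", "lower", 45, "%energy",
                    nutrient = "carbohydrate"),
    constraint_spec("carbohydrate_upper", "upper", 60, "%energy",
                    nutrient = "carbohydrate"),
    constraint_spec("free_sugars_upper", "upper", 10, "%energy",
                    nutrient = "free_sugars",
                    notes = "free sugars below 10% of total energy intake"),
    constraint_spec("fibre_lower", "lower", 25, "g/day", nutrient = "fibre"),
    constraint_spec("salt_upper", "upper", 6, "g/day", nutrient = "salt"),
    constraint_spec("water_lower_man", "lower", 2500, "g/day",
                    nutrient = "water", applies_to = "man",
                    notes = "water from beverages and from food"),
    constraint_spec("water_lower_woman", "lower", 2000, "g/day",
                    nutrient = "water", applies_to = "woman"),
    constraint_spec("water_upper", "upper", 1.3, "multiplier-of-lower-bound",
                    nutrient = "water",
                    notes = "cap 30% above the recommended water amount"),
    constraint_spec("thiamin_lower", "lower", 0.1, "mg/MJ",
                    nutrient = "thiamin"),
    constraint_spec("vitamin_c_lower_man", "lower", 110, "mg/day",
                    nutrient = "vitamin_c", applies_to = "man"),
    constraint_spec("vitamin_c_lower_woman", "lower", 95, "mg/day",
                    nutrient = "vitamin_c", applies_to = "woman"),
    constraint_spec("vitamin_d_lower", "lower", 5, "ug/day",
                    nutrient = "vitamin_d",
                    notes = "floor; endogenous synthesis covers the remainder"),
    constraint_spec("calcium_lower", "lower", 950, "mg/day",
                    nutrient = "calcium"),
    constraint_spec("iron_lower_man", "lower", 11, "mg/day",
                    nutrient = "iron", applies_to = "man"),
    constraint_spec("iron_lower_woman", "lower", 16, "mg/day",
                    nutrient = "iron", applies_to = "woman"),
    constraint_spec("fruit_veg_lower", "lower", 7, "%energy",
                    categories = c("fruits", "vegetables"),
                    energy_density_kcal_per_100g = fruit_veg_density(),
                    notes = "fruit+veg supply 7-14% of energy"),
    constraint_spec("fruit_veg_upper", "upper", 14, "%energy",
                    categories = c("fruits", "vegetables"),
                    energy_density_kcal_per_100g = fruit_veg_density()),
    constraint_spec("caffeine_upper", "upper", 800, "g/day",
                    tags = c("coffee", "tea"), scale_by_bodyweight = TRUE,
                    ref_bodyweight_kg = 82,
                    notes = "4 cups x 200 g; 400 mg caffeine at <100 mg/cup")
  )
  class(cs) <- c("constraint_set", "list")
  cs
}

#' Read a constraint set from YAML
#'
#' The file has keys \code{energy_factors_kj_per_g} (optional override) and
#' \code{constraints}, a list of entries matching \code{constraint_spec}'s
#' arguments.
#'
#' @param path YAML file.
#' @return A \code{constraint_set}; the energy-factor override, if present,
#'   is attached as attribute \code{energy_factors}.
#' @export
read_constraints <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constraints)) stop("constraint config has no 'constraints' key")
  cs <- lapply(cfg$constraints, function(x) {
    do.call(constraint_spec, c(
      list(id = x$id, bound = x$bound, value = x$value, unit = x$unit),
      x[intersect(names(x), c("nutrient", "codes", "categories", "tags",
                              "applies_to", "energy_density_kcal_per_100g",
                              "scale_by_bodyweight", "ref_bodyweight_kg",
                              "notes"))]))
  })
  class(cs) <- c("constraint_set", "list")
  if (!is.null(cfg$energy_factors_kj_per_g))
    attr(cs, "energy_factors") <- unlist(cfg$energy_factors_kj_per_g)
  cs
}

#' Write a constraint set to YAML
#' @param specs a \code{constraint_set}
#' @param path output file
#' @return \code{path}, invisibly.
#' @export
write_constraints <- function(specs, path) {
  strip <- function(s) {
    s <- unclass(s)
    s[!vapply(s, is.null, TRUE)]
  }
  cfg <- list(energy_factors_kj_per_g = as.list(energy_factors_kj()),
              constraints = lapply(specs, strip))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
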