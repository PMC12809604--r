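man <- person_profile("man")
woman <- person_profile("woman")

test_that("percent-of-energy recommendations convert via the energy factors", {
  # 10 %E free sugars at 9.4 MJ with the 17 kJ/g carbohydrate factor
  expect_equal(convert_percent_energy(10, "free_sugars", man),
               0.10 * 9400 / 17)
  expect_equal(convert_percent_energy(0, "free_sugars", man), 0)
  # woman's bound scales with the energy ratio
  expect_equal(convert_percent_energy(10, "free_sugars", woman) /
                 convert_percent_energy(10, "free_sugars", man), 7.55 / 9.4)
  expect_error(convert_percent_energy(10, "vitamin_c", man), "energy factor")
})

test_that("bodyweight and per-megajoule recommendations convert by products", {
  expect_equal(convert_bodyweight(0.83, man), 0.83 * 82)
  expect_equal(convert_bodyweight(0, man), 0)
  expect_equal(convert_bodyweight(0.83, man) / convert_bodyweight(0.83, woman),
               82 / 66)
  expect_equal(convert_per_megajoule(0.1, man), 0.94)
  expect_equal(convert_per_megajoule(0, man), 0)
  expect_equal(convert_per_megajoule(0.1, woman) / convert_per_megajoule(0.1, man),
               7.55 / 9.4)
})

test_that("fruit and vegetable bounds follow the portion-weighted density", {
  # 2 fruit portions @ 50 kcal + 3 vegetable portions @ 20 kcal per 100 g
  expect_equal(fruit_veg_density(), (2 * 50 + 3 * 20) / 5)
  expect_equal(fruit_veg_density(), 32)
  reg <- toy_registry()
  fv <- build_fruit_veg_bounds(man, reg)
  expect_equal(fv[[1]]$rhs, 0.07 * (9.4 * 1000 / 4.184) / 0.32)
  expect_equal(fv[[1]]$rhs, 491.4555, tolerance = 1e-4)
  # 14 %E is exactly twice 7 %E
  expect_equal(fv[[2]]$rhs, 2 * fv[[1]]$rhs)
  # bounds sum over exactly the fruit + vegetable groups
  expect_setequal(names(fv[[1]]$coef), c("C1", "D1"))
  reg_nofv <- food_registry(data.frame(code = "A1", name = "bread",
                                       category = "foods rich in carbohydrates"))
  expect_error(build_fruit_veg_bounds(man, reg_nofv), "no fruit")
})

test_that("water bounds cover all groups and cap at +30 %", {
  nut <- toy_nutrients()
  wb <- build_water_bounds(2500, nut)
  expect_equal(wb[[1]]$rhs, 2500)
  expect_equal(wb[[2]]$rhs, 1.3 * 2500)
  expect_length(wb[[1]]$coef, nrow(nut))
  # linear accumulation: 100 g of a food with 85 g water/100 g adds 85 g
  coef <- stats::setNames(c(0.85, 0.50, 0.10), c("x", "y", "z"))
  b <- linear_bound("w", coef, ">=", 0)
  diet <- c(x = 100, y = 200, z = 300)
  chk <- check_bounds(diet, list(b))
  expect_equal(unname(attr(chk, "slack")["w"]), 85 + 100 + 30)
})

test_that("the caffeine cap is 4 cups for a man, bodyweight-scaled for a woman", {
  reg <- food_registry(data.frame(
    code = c("K1", "K2"), name = c("coffee", "tea"),
    category = c("others", "others"), tag = c("coffee", "tea")))
  expect_equal(400 / 100, 4)  # safe intake over per-cup content
  bm <- build_caffeine_bounds(man, reg)
  expect_equal(bm$rhs, 4 * 200)
  expect_setequal(names(bm$coef), c("K1", "K2"))
  bw <- build_caffeine_bounds(woman, reg)
  expect_equal(bw$rhs, 800 * 66 / 82)
  expect_equal(bw$rhs, 643.9024, tolerance = 1e-4)
  expect_error(build_caffeine_bounds(man, toy_registry()), "no coffee")
})

test_that("assembly converts every unit and handles special rules", {
  reg <- toy_registry()
  nut <- toy_nutrients()
  expect_length(assemble_constraints(list(), reg, nut, man), 0)
  # vitamin D floor arrives unchanged at 5 ug/day
  nut2 <- cbind(nut, vitamin_d = c(0, 0.5, 0, 0, 0.3))
  class(nut2) <- class(nut)
  vd <- assemble_constraints(
    list(constraint_spec("vitd", "lower", 5, "ug/day",
                         nutrient = "vitamin_d")), reg, nut2, man)
  expect_equal(vd[[1]]$rhs, 5)
  expect_equal(vd[[1]]$dir, ">=")
  # g/day passes through; coefficient is the per-gram content
  fb <- assemble_constraints(
    list(constraint_spec("fibre", "lower", 25, "g/day", nutrient = "fibre")),
    reg, nut, man)
  expect_equal(fb[[1]]$rhs, 25)
  expect_equal(unname(fb[[1]]$coef["A1"]), nut["A1", "fibre"] / 100)
  # the multiplier unit resolves against the matching lower bound
  wb <- assemble_constraints(
    list(constraint_spec("w_lo", "lower", 2000, "g/day", nutrient = "water"),
         constraint_spec("w_hi", "upper", 1.3, "multiplier-of-lower-bound",
                         nutrient = "water")), reg, nut, man)
  expect_equal(wb[[2]]$rhs, 2600)
  expect_error(assemble_constraints(
    list(constraint_spec("bad", "lower", 1, "g/day", nutrient = "selenium")),
    reg, nut, man), "unknown nutrient")
})

test_that("every conversion is homogeneous of degree one in the recommendation", {
  reg <- toy_registry()
  nut <- toy_nutrients()
  mk <- function(value, unit) constraint_spec("h", "upper", value, unit,
                                              nutrient = "free_sugars")
  for (unit in c("g/day", "%energy", "g/kg-bw")) {
    r1 <- assemble_constraints(list(mk(3, unit)), reg, nut, man)[[1]]$rhs
    r2 <- assemble_constraints(list(mk(6, unit)), reg, nut, man)[[1]]$rhs
    expect_equal(r2, 2 * r1, info = unit)
  }
})

test_that("gender ratios of converted bounds match the energy and weight ratios", {
  reg <- toy_registry()
  nut <- toy_nutrients()
  ratio <- function(unit, nutrient = "protein") {
    s <- list(constraint_spec("r", "lower", 1.7, unit, nutrient = nutrient))
    assemble_constraints(s, reg, nut, man)[[1]]$rhs /
      assemble_constraints(s, reg, nut, woman)[[1]]$rhs
  }
  expect_equal(ratio("%energy"), 9.4 / 7.55)
  expect_equal(ratio("g/kg-bw"), 82 / 66)
  # mg/MJ via a nutrient carried in mg
  nut3 <- cbind(nut, thiamin = rep(0.1, 5))
  class(nut3) <- class(nut)
  s <- list(constraint_spec("t", "lower", 0.1, "mg/MJ", nutrient = "thiamin"))
  expect_equal(assemble_constraints(s, reg, nut3, man)[[1]]$rhs /
                 assemble_constraints(s, reg, nut3, woman)[[1]]$rhs, 9.4 / 7.55)
})

test_that("builder and independent checker agree on random toy diets", {
  reg <- toy_registry()
  nut <- toy_nutrients()
  bounds <- assemble_constraints(list(
    constraint_spec("sug", "upper", 10, "%energy", nutrient = "free_sugars"),
    constraint_spec("fib", "lower", 25, "g/day", nutrient = "fibre"),
    constraint_spec("fv", "lower", 7, "%energy",
                    categories = c("fruits", "vegetables"),
                    energy_density_kcal_per_100g = 32)), reg, nut, man)
  set.seed(11)
  for (rep in 1:20) {
    diet <- stats::setNames(stats::runif(5, 0, 800), reg$code)
    chk <- check_bounds(diet, bounds)
    # independent accumulation loop, written out longhand
    manual <- logical(length(bounds))
    for (k in seq_along(bounds)) {
      b <- bounds[[k]]
      tot <- 0
      for (code in names(b$coef))
        if (code %in% names(diet)) tot <- tot + b$coef[[code]] * diet[[code]]
      manual[k] <- if (b$dir == "<=") tot <= b$rhs + 1e-7 else
        tot >= b$rhs - 1e-7
    }
    expect_equal(as.logical(chk), manual)
  }
})
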