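test_that("the same seed yields byte-identical bundles", {
  cfg <- synth_config(n_countries = 2, n_groups = 12, seed = 77)
  b1 <- synth_generate(cfg)
  b2 <- synth_generate(cfg)
  expect_identical(serialize(b1, NULL), serialize(b2, NULL))
})

test_that("a fully healthy bundle is feasible at the 10 % floor with zero departure", {
  b <- synth_generate(synth_config(n_countries = 1, seed = 5,
                                   unhealthiness = 0))
  for (p in b$profiles) {
    fit <- fit_diet(p, b$nutrients, b$constraints,
                    person_profile(p$gender), b$registry)
    expect_equal(fit$floor, 0.10)
    expect_equal(fit$tdmi, 0, tolerance = 1e-9)
    expect_equal(nrow(fit$trace), 1)
  }
})

test_that("incomes span the configured range with exact endpoints", {
  b <- synth_generate(synth_config(n_countries = 5, n_groups = 12, seed = 1))
  expect_equal(min(b$incomes), 3284)
  expect_equal(max(b$incomes), 34472)
  expect_false(is.unsorted(b$incomes))
})

test_that("generated nutrient vectors keep water plus macro mass within 100 g", {
  b <- synth_generate(synth_config(n_countries = 1, seed = 2))
  nut <- b$nutrients
  mass <- nut[, "protein"] + nut[, "fat"] + nut[, "carbohydrate"] +
    nut[, "fibre"] + nut[, "water"] + nut[, "salt"]
  expect_true(all(mass <= 100 + 1))
  # declared energy is exactly consistent with the energy factors
  pred <- (17 * (nut[, "protein"] + nut[, "carbohydrate"]) +
             37 * nut[, "fat"] + 8 * nut[, "fibre"]) / 4.184
  expect_equal(unname(nut[, "energy"]), unname(pred), tolerance = 1e-12)
})

test_that("price observation medians track the configured group levels", {
  # the mineral-water group has a fixed base price of 0.5 EUR/kg; the
  # lognormal median equals that base, so sample medians should centre on it
  meds <- vapply(1:20, function(s) {
    b <- synth_generate(synth_config(n_countries = 1, n_groups = 12,
                                     seed = 1000 + s))
    code <- b$registry$code[b$registry$tag == "water"]
    stats::median(b$prices[[code]])
  }, numeric(1))
  expect_equal(mean(meds), 0.5, tolerance = 0.1)
  expect_gte(min(lengths(synth_generate(
    synth_config(n_countries = 1, n_groups = 12, seed = 1))$prices)), 30)
})

test_that("raising unhealthiness raises the optimal departure on average", {
  tdmi_at <- function(u, seed) {
    b <- synth_generate(synth_config(n_countries = 1, n_groups = 20,
                                     seed = seed, unhealthiness = u))
    p <- Filter(function(x) x$gender == "man", b$profiles)[[1]]
    fit_diet(p, b$nutrients, b$constraints, person_profile("man"),
             b$registry)$tdmi
  }
  seeds <- c(51, 52, 53)
  lo <- mean(vapply(seeds, function(s) tdmi_at(0.1, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) tdmi_at(0.6, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("the constructed relaxation case is certified at each floor", {
  mi <- make_infeasible_case(0.08, synth_config(seed = 3))
  person <- person_profile("man")
  prof <- Filter(function(p) p$gender == "man", mi$profiles)[[1]]
  fit <- fit_diet(prof, mi$nutrients, mi$constraints, person, mi$registry)
  expect_equal(fit$floor, 0.08)
  expect_equal(nrow(fit$trace), 3)
  expect_equal(fit$trace$status, c("infeasible", "infeasible", "optimal"))
  # boundary: a 10 % target is just a plain feasible bundle
  mi10 <- make_infeasible_case(0.10, synth_config(seed = 3))
  prof10 <- Filter(function(p) p$gender == "man", mi10$profiles)[[1]]
  fit10 <- fit_diet(prof10, mi10$nutrients, mi10$constraints, person,
                    mi10$registry)
  expect_equal(fit10$floor, 0.10)
})

test_that("configs are validated", {
  expect_error(synth_config(n_groups = 5), "categories")
  expect_error(synth_config(unhealthiness = 1.5), "unhealthiness")
  expect_error(synth_config(energy_sd = -1), "nonnegative")
})

test_that("bundles round-trip through a plain-text directory", {
  b <- synth_generate(synth_config(n_countries = 2, n_groups = 12, seed = 7))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_setequal(list.files(dir),
                  c("registry.yaml", "nutrients.csv", "consumption.csv",
                    "prices.csv", "pli.csv", "incomes.csv",
                    "constraints.yaml"))
  reg <- read_registry(file.path(dir, "registry.yaml"))
  expect_equal(reg$code, b$registry$code)
  nut <- read_nutrients(file.path(dir, "nutrients.csv"))
  expect_equal(nut[rownames(b$nutrients), colnames(b$nutrients)],
               unclass(b$nutrients)[, ], ignore_attr = TRUE)
  profs <- suppressMessages(
    read_consumption(file.path(dir, "consumption.csv"), reg))
  expect_length(profs, 4)
  cons <- read_constraints(file.path(dir, "constraints.yaml"))
  expect_length(cons, length(b$constraints))
  expect_equal(cons[[1]]$id, b$constraints[[1]]$id)
})
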