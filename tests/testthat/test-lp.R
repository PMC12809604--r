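test_that("TDMI sums standardised absolute departures", {
  expect_equal(tdmi(c(100, 200), c(100, 200)), 0)
  # |150-100|/100 + |100-200|/200 = 0.5 + 0.5
  expect_equal(tdmi(c(150, 100), c(100, 200)), 1.0)
  # homogeneity of degree zero: rescaling both diets leaves TDMI unchanged
  expect_equal(tdmi(7 * c(150, 100), 7 * c(100, 200)), 1.0)
  expect_error(tdmi(c(1, 2), c(1, 0)), "nonpositive")
  expect_error(tdmi(1:3, 1:2), "length")
})

test_that("linearization produces 3n variables and valid floors", {
  sC <- stats::setNames(c(100, 50, 20), c("a", "b", "c"))
  m <- linearize(sC, list(), floor = 0.10)
  expect_equal(m$n_var, 9)
  expect_equal(nrow(m$A3), 3)   # one identity per group
  expect_error(linearize(sC, list(), floor = 1), "floor")
  expect_error(linearize(numeric(0), list()), "empty")
  expect_error(linearize(c(a = 0, b = 1), list()), "positive")
})

test_that("a diet already satisfying all bounds is returned unchanged", {
  sC <- stats::setNames(c(300, 150, 80), c("a", "b", "c"))
  bounds <- list(linear_bound("u", c(a = 1, b = 1, c = 1), "<=", 1000))
  sol <- solve_diet_lp(linearize(sC, bounds, floor = 0.10))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
  expect_equal(sol$X, sC, tolerance = 1e-10)
})

test_that("a 3-group optimum matches the exhaustive grid search", {
  sC <- stats::setNames(c(10, 8, 6), c("a", "b", "c"))
  # cap a weighted sum well below its observed value
  bounds <- list(linear_bound("cap", c(a = 1, b = 0.5, c = 0.25), "<=", 10))
  sol <- solve_diet_lp(linearize(sC, bounds, floor = 0.10))
  expect_equal(sol$status, "optimal")
  gmin <- grid_search_tdmi(sC, bounds, floor = 0.10, grid_max = 16)
  expect_lte(sol$objective, gmin + 1e-9)
  expect_lte(gmin - sol$objective, sum(1 / sC))
})

test_that("contradictory bounds give an infeasibility certificate", {
  sC <- stats::setNames(c(100, 50), c("a", "b"))
  bounds <- list(linear_bound("lo", c(a = 1, b = 1), ">=", 500),
                 linear_bound("hi", c(a = 1, b = 1), "<=", 100))
  sol <- solve_diet_lp(linearize(sC, bounds, floor = 0.10))
  expect_equal(sol$status, "infeasible")
  expect_null(sol$X)
  expect_true(is.na(sol$objective))
})

test_that("repeated solves are bit-identical", {
  fit1 <- small_fit(seed = 13)
  fit2 <- small_fit(seed = 13)
  expect_identical(coef(fit1), coef(fit2))
  expect_identical(fit1$tdmi, fit2$tdmi)
})

test_that("the relaxation loop solves at 10 % when feasible and logs one attempt", {
  sC <- stats::setNames(c(300, 150, 80), c("a", "b", "c"))
  bounds <- list(linear_bound("u", c(a = 1, b = 1, c = 1), "<=", 1000))
  sol <- solve_with_relaxation(sC, bounds)
  expect_equal(sol$floor, 0.10)
  expect_equal(nrow(sol$trace), 1)
  expect_error(solve_with_relaxation(sC, bounds, step = 0), "step")
})

test_that("an instance solvable only at 8 % is relaxed in three logged steps", {
  # cap total mass of group a at 8.5 % of its observed value: floors of 10 %
  # and 9 % are contradictory, 8 % is not
  sC <- stats::setNames(c(200, 100), c("a", "b"))
  bounds <- list(linear_bound("cap_a", c(a = 1), "<=", 0.085 * 200))
  sol <- solve_with_relaxation(sC, bounds)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$floor, 0.08)
  expect_equal(sol$trace$status, c("infeasible", "infeasible", "optimal"))
  # oracle: independent per-floor solves agree with the trace
  for (k in seq_len(nrow(sol$trace))) {
    ind <- solve_diet_lp(linearize(sC, bounds, floor = sol$trace$floor[k]))
    expect_equal(ind$status, sol$trace$status[k])
  }
})

test_that("exhausted relaxation reports infeasible with a full trace", {
  sC <- stats::setNames(c(100, 100), c("a", "b"))
  bounds <- list(linear_bound("lo", c(a = 1, b = 1), ">=", 900),
                 linear_bound("hi", c(a = 1, b = 1), "<=", 100))
  sol <- solve_with_relaxation(sC, bounds, start_floor = 0.10,
                               step = 0.01, min_floor = 0)
  expect_equal(sol$status, "infeasible")
  expect_equal(nrow(sol$trace), 11)
  expect_true(all(sol$trace$status == "infeasible"))
})

test_that("tightening a bound never decreases the optimal departure", {
  set.seed(17)
  for (rep in 1:5) {
    inst <- random_lp_instance(4, seed = 100 + rep)
    ub <- Filter(function(b) b$dir == "<=", inst$bounds)
    if (!length(ub)) next
    s1 <- solve_diet_lp(linearize(inst$sC, inst$bounds, floor = 0.10))
    tight <- lapply(inst$bounds, function(b) {
      if (b$dir == "<=") b$rhs <- b$rhs * 0.9 else b$rhs <- b$rhs * 1.05
      b
    })
    s2 <- solve_diet_lp(linearize(inst$sC, tight, floor = 0.10))
    if (s1$status == "optimal" && s2$status == "optimal")
      expect_gte(s2$objective + 1e-9, s1$objective)
  }
})

test_that("optimal departure is non-increasing as the floor decreases", {
  inst <- random_lp_instance(5, seed = 42)
  vals <- vapply(c(0.10, 0.05, 0), function(f) {
    s <- solve_diet_lp(linearize(inst$sC, inst$bounds, floor = f))
    if (s$status == "optimal") s$objective else Inf
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("returned solutions satisfy every bound and floor", {
  for (seed in 1:5) {
    inst <- random_lp_instance(4, seed = 200 + seed)
    s <- solve_diet_lp(linearize(inst$sC, inst$bounds, floor = 0.10))
    if (s$status != "optimal") next
    expect_true(all(check_bounds(s$X, inst$bounds, tol = 1e-6)))
    expect_true(all(s$X >= 0.10 * inst$sC - 1e-6))
  }
})

test_that("fit_diet drops never-consumed groups from the model dimension", {
  b <- synth_generate(synth_config(n_countries = 1, n_groups = 12, seed = 3))
  prof <- b$profiles[[1]]
  q <- prof$quantities
  q[2] <- 0
  prof2 <- consumption_profile(prof$country, q, gender = prof$gender)
  fit <- fit_diet(prof2, b$nutrients, b$constraints,
                  person_profile(prof$gender), b$registry)
  expect_false(names(q)[2] %in% names(coef(fit)))
  expect_true(names(q)[2] %in% fit$dropped)
  expect_equal(length(coef(fit)), 11)
})
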