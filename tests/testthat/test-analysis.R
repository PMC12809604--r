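test_that("category aggregation sums member groups and conserves mass", {
  reg <- toy_registry()
  q <- stats::setNames(c(100, 200, 50, 30, 20), reg$code)
  agg <- aggregate_categories(q, reg)
  expect_equal(unname(agg["fruits"]), 50)
  expect_equal(unname(agg["eggs"]), 0)        # empty category
  expect_equal(sum(agg), sum(q))              # totals conserve diet mass
  expect_error(aggregate_categories(c(ZZ = 1), reg), "not in registry")
})

test_that("percent change mirrors the headline arithmetic", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 330.9), 230.9)
  expect_equal(percent_change(100, 50), -50)
  expect_true(is.na(percent_change(0, 10)))
})

test_that("correlation is exact on affine relations and matches a hand computation", {
  obs <- c(3, 7, 2, 9, 5)
  expect_equal(cross_country_correlation(obs, obs)$r, 1)
  expect_equal(cross_country_correlation(obs, 2 + 3 * obs)$r, 1)
  opt <- c(4, 6, 3, 10, 4)
  # hand covariance computation as the oracle
  r_hand <- sum((obs - mean(obs)) * (opt - mean(opt))) /
    sqrt(sum((obs - mean(obs))^2) * sum((opt - mean(opt))^2))
  res <- cross_country_correlation(obs, opt)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  # significance from the t-transform with n-2 df, two-sided
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$sig5, p_hand < 0.05)
})

test_that("zero-variance vectors give a flagged undefined correlation", {
  res <- cross_country_correlation(c(1, 1, 1), c(2, 3, 4))
  expect_true(is.na(res$r))
  expect_true(is.na(res$sig5))
  expect_error(cross_country_correlation(1:2, 1:2), "at least 3")
})

test_that("bisector classification follows the sign of the change", {
  expect_equal(bisector_classification(100, 150), "above")
  expect_equal(bisector_classification(100, 100), "on")
  expect_equal(bisector_classification(100, 50), "below")
  expect_equal(bisector_classification(c(1, 2, 3), c(2, 2, 1)),
               c("above", "on", "below"))
})

test_that("engineered fruit/vegetable deficits classify above the bisector everywhere", {
  b <- synth_generate(synth_config(n_countries = 3, n_groups = 12, seed = 29))
  # push every country far below the fruit/vegetable energy-share floor
  fv <- b$registry$code[b$registry$category %in% c("fruits", "vegetables")]
  deficient <- lapply(Filter(function(p) p$gender == "man", b$profiles),
                      function(p) {
                        q <- p$quantities
                        q[fv] <- q[fv] * 0.2
                        consumption_profile(p$country, q, gender = "man")
                      })
  fits <- lapply(deficient,
                 function(p) fit_diet(p, b$nutrients, b$constraints,
                                      person_profile("man"), b$registry))
  # the energy-share rule binds the fruit + vegetable total, so the joint
  # aggregate must rise above the bisector in every country
  obs <- vapply(fits, function(f) {
    a <- aggregate_categories(f$sC, f$registry)
    a[["fruits"]] + a[["vegetables"]]
  }, numeric(1))
  opt <- vapply(fits, function(f) {
    a <- aggregate_categories(coef(f), f$registry)
    a[["fruits"]] + a[["vegetables"]]
  }, numeric(1))
  expect_true(all(bisector_classification(obs, opt) == "above"))
})

test_that("the summary uses the mean of per-country changes, not the change of means", {
  reg <- toy_registry()
  # two fabricated fits with very different magnitudes so the two statistics
  # disagree strongly
  mk_fit <- function(sC, X) {
    structure(list(sC = sC, coefficients = X, status = "optimal",
                   registry = reg, person = person_profile("man")),
              class = "diet_fit")
  }
  f1 <- mk_fit(stats::setNames(c(10, 1, 1, 1, 1), reg$code),
               stats::setNames(c(20, 1, 1, 1, 1), reg$code))   # +100 % carbs
  f2 <- mk_fit(stats::setNames(c(1000, 1, 1, 1, 1), reg$code),
               stats::setNames(c(1000, 1, 1, 1, 1), reg$code)) # 0 % carbs
  cs <- change_summary(list(f1, f2))
  carbs <- cs$mean_change_pct[cs$category == "foods rich in carbohydrates"]
  expect_equal(carbs, (100 + 0) / 2)              # mean of changes
  change_of_means <- percent_change((10 + 1000) / 2, (20 + 1000) / 2)
  expect_false(isTRUE(all.equal(carbs, change_of_means)))
})
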