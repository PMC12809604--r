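# Shared fixtures and independent oracles, all built in code.

# A tiny 5-group registry covering several categories.
toy_registry <- function() {
  food_registry(data.frame(
    code = c("A1", "B1", "C1", "D1", "E1"),
    name = c("bread", "milk", "apples", "spinach", "chocolate"),
    category = c("foods rich in carbohydrates", "milk and dairy products",
                 "fruits", "vegetables", "sweets and snacks"),
    stringsAsFactors = FALSE))
}

# Matching toy nutrient table (per 100 g, internally consistent energy).
toy_nutrients <- function() {
  keys <- c("energy", "protein", "fat", "carbohydrate", "fibre", "water",
            "free_sugars")
  mk <- function(protein, fat, carbohydrate, fibre, water, sugars) {
    e <- (17 * (protein + carbohydrate) + 37 * fat + 8 * fibre) / 4.184
    c(e, protein, fat, carbohydrate, fibre, water, sugars)
  }
  mat <- rbind(A1 = mk(8, 2, 50, 5, 33, 2),
               B1 = mk(3.4, 3.5, 4.8, 0, 87, 0),
               C1 = mk(0.3, 0.2, 12, 2, 84, 1),
               D1 = mk(2.5, 0.3, 2, 2, 92, 0),
               E1 = mk(5, 30, 58, 3, 2, 50))
  colnames(mat) <- keys
  nutrient_table(mat)
}

# Exhaustive integer-grid minimiser of TDMI over the feasible region.
# Independent of the LP path: plain enumeration + direct arithmetic.
grid_search_tdmi <- function(sC, bounds, floor, grid_max) {
  n <- length(sC)
  pts <- as.matrix(expand.grid(rep(list(0:grid_max), n)))
  colnames(pts) <- names(sC)
  feas <- rep(TRUE, nrow(pts))
  for (j in seq_len(n))
    feas <- feas & (pts[, j] >= floor * sC[j] - 1e-9)
  for (b in bounds) {
    idx <- match(names(b$coef), names(sC))
    keep <- !is.na(idx)
    lhs <- as.vector(pts[, idx[keep], drop = FALSE] %*% b$coef[keep])
    feas <- feas & if (b$dir == "<=") lhs <= b$rhs + 1e-9 else
      lhs >= b$rhs - 1e-9
  }
  if (!any(feas)) return(Inf)
  dev <- abs(t(pts[feas, , drop = FALSE]) - sC) / sC
  min(colSums(dev))
}

# Random small LP instance whose optimum stays inside the grid box:
# coefficients bounded away from zero and at most one (gently) violated
# lower bound, so the optimal displacement cannot leave the box.
random_lp_instance <- function(n, seed) {
  set.seed(seed)
  ranges <- list(`4` = c(4, 12, 20), `5` = c(3, 8, 14), `6` = c(2, 5, 10))
  r <- ranges[[as.character(n)]]
  sC <- stats::setNames(sample(r[1]:r[2], n, replace = TRUE),
                        paste0("g", seq_len(n)))
  n_upper <- sample(0:2, 1)
  with_lower <- n_upper == 0
  bounds <- list()
  for (k in seq_len(n_upper)) {
    coef <- stats::setNames(round(stats::runif(n, 0.4, 1), 2), names(sC))
    bounds <- c(bounds, list(linear_bound(
      paste0("u", k), coef, "<=",
      round(stats::runif(1, 0.5, 0.9) * sum(coef * sC), 2))))
  }
  if (with_lower) {
    coef <- stats::setNames(round(stats::runif(n, 0.4, 1), 2), names(sC))
    bounds <- c(bounds, list(linear_bound(
      "l1", coef, ">=",
      round(stats::runif(1, 1.02, 1.08) * sum(coef * sC), 2))))
  }
  list(sC = sC, bounds = bounds, grid_max = r[3])
}

# Small solved fit for IO/method tests (12 groups, one country).
small_fit <- function(seed = 21, unhealthiness = 0.3, gender = "man") {
  b <- synth_generate(synth_config(n_countries = 1, n_groups = 12,
                                   seed = seed,
                                   unhealthiness = unhealthiness))
  prof <- Filter(function(p) p$gender == gender, b$profiles)[[1]]
  fit_diet(prof, b$nutrients, b$constraints, person_profile(gender),
           b$registry)
}
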