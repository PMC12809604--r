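#' Lower-percentile price of a food group
#'
#' Price observations within a food group vary with brand and point of sale;
#' basket costing therefore uses lower percentiles of the observation set
#' rather than the mean.  The estimator is the linear-interpolation
#' order-statistic quantile (the convention where the 50th percentile is the
#' sample median; \code{stats::quantile} type 7 by default).
#'
#' @param observations numeric vector of prices (EUR/kg), all > 0.
#' @param q percentile in (0, 100).
#' @param type \code{stats::quantile} algorithm type.
#' @return Price in EUR/kg.
#' @export
percentile_price <- function(observations, q, type = 7) {
  if (!length(observations)) stop("empty price observation set")
  if (any(observations <= 0)) stop("price observations must be positive")
  if (q <= 0 || q >= 100) stop("percentile must be in (0, 100)")
  unname(stats::quantile(observations, q / 100, type = type, names = FALSE))
}

#' Transfer a price between countries via price level indices
#'
#' Price observations exist for one base country only; other countries'
#' prices are derived through their relative price level indices:
#' price_target = price_base x PLI_target / PLI_base.
#'
#' @param base_price EUR/kg in the base country.
#' @param pli_target,pli_base price level indices (> 0).
#' @return EUR/kg in the target country.
#' @export
transfer_price <- function(base_price, pli_target, pli_base) {
  if (any(pli_target <= 0) || any(pli_base <= 0))
    stop("price level indices must be positive")
  base_price * pli_target / pli_base
}

#' Daily cost of an optimised basket
#'
#' @param X named quantities in g/day (e.g. \code{coef(fit)}).
#' @param prices named EUR/kg vector covering every group in \code{X}.
#' @return Cost in EUR/day: sum of X/1000 x price.
#' @export
cost_of_basket <- function(X, prices) {
  miss <- setdiff(names(X), names(prices))
  bad <- names(X)[is.na(prices[names(X)])]
  miss <- union(miss, bad)
  if (length(miss))
    stop("unpriced food group(s): ", paste(miss, collapse = ", "))
  sum(X / 1000 * prices[names(X)])
}

#' Food cost as a share of income
#'
#' @param cost EUR/day.
#' @param income median equivalised net income, EUR/year (> 0).
#' @param days_per_year annualisation factor.
#' @return Percentage of income.
#' @export
income_share <- function(cost, income, days_per_year = 365) {
  if (any(income <= 0)) stop("income must be positive")
  cost * days_per_year / income * 100
}

#' Highest price percentile affordable under an allowance
#'
#' Compares the per-percentile costs of a basket with a daily food allowance
#' (e.g. the food component of a national social benefit) and returns the
#' largest percentile whose cost stays within it.
#'
#' @param costs numeric vector of EUR/day costs named by percentile, in
#'   ascending percentile order.
#' @param allowance EUR/day (> 0).
#' @return The largest affordable percentile, or \code{NA} if even the
#'   lowest-percentile cost exceeds the allowance.
#' @export
benchmark_against_allowance <- function(costs, allowance) {
  if (!length(costs)) stop("empty percentile cost grid")
  if (allowance <= 0) stop("allowance must be positive")
  p <- as.numeric(names(costs))
  if (any(is.na(p))) stop("costs must be named by percentile")
  ok <- p[costs <= allowance]
  if (!length(ok)) NA_real_ else max(ok)
}

#' Read price observations from CSV
#'
#' Expected columns: \code{code}, \code{price_eur_per_kg}.  Multiple rows per
#' code form that group's observation set.
#'
#' @param path CSV file.
#' @return Named list of numeric vectors, one per food-group code.
#' @export
read_prices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  miss <- setdiff(c("code", "price_eur_per_kg"), names(df))
  if (length(miss)) stop("price file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$price_eur_per_kg <= 0)) stop("nonpositive price observation")
  split(df$price_eur_per_kg, df$code)
}

#' Read price level indices from CSV
#'
#' Expected columns: \code{country}, \code{code}, \code{index}.
#'
#' @param path CSV file.
#' @return data.frame of PLIs.
#' @export
read_pli <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  miss <- setdiff(c("country", "code", "index"), names(df))
  if (length(miss)) stop("PLI file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$index <= 0)) stop("nonpositive price level index")
  df
}

#' Read median equivalised net incomes from CSV
#'
#' Expected columns: \code{country},
#' \code{median_equiv_net_income_eur_year}.
#'
#' @param path CSV file.
#' @return Named numeric vector, country -> EUR/year.
#' @export
read_incomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("country", "median_equiv_net_income_eur_year"), names(df))
  if (length(miss)) stop("income file lacks column(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(df$median_equiv_net_income_eur_year, df$country)
}

#' Food Reference Budgets for a set of fitted diets
#'
#' Prices each optimised basket at the requested lower price percentiles.
#' Percentile prices are computed on the base country's observation sets and
#' transferred to each diet's country through that country's price level
#' indices; the daily cost is then expressed as a share of the country's
#' median equivalised net income.  Countries without PLIs (or income) are
#' skipped with a warning, mirroring how a missing-index country drops out of
#' the budget stage while keeping its optimised diet.
#'
#' @param fits list of \code{diet_fit} objects (status optimal).
#' @param prices named list of price observation vectors (base country).
#' @param pli PLI data.frame (\code{country}, \code{code}, \code{index});
#'   must include the base country.
#' @param incomes named EUR/year vector.
#' @param base_country country whose prices the observations describe.
#' @param percentiles percentiles to evaluate.
#' @return A \code{budget_table} data.frame: country, gender, percentile,
#'   cost_eur_day, annual_cost_eur, income_share_pct.
#' @export
budget_table <- function(fits, prices, pli, incomes, base_country,
                         percentiles = c(20, 30, 40, 50)) {
  if (is.unsorted(percentiles)) stop("percentiles must be ascending")
  base_pli <- pli[pli$country == base_country, ]
  if (!nrow(base_pli)) stop("no PLIs for base country ", base_country)
  rows <- list()
  for (fit in fits) {
    if (fit$status != "optimal") next
    X <- coef(fit)
    ctry <- fit$country
    cpli <- pli[pli$country == ctry, ]
    if (!nrow(cpli)) {
      warning("no price level indices for ", ctry, "; skipped in budgets")
      next
    }
    if (!ctry %in% names(incomes)) {
      warning("no income for ", ctry, "; skipped in budgets")
      next
    }
    for (q in percentiles) {
      pp <- vapply(names(X), function(code) {
        obs <- prices[[code]]
        if (is.null(obs)) stop("unpriced food group: ", code)
        p0 <- percentile_price(obs, q)
        it <- cpli$index[cpli$code == code]
        ib <- base_pli$index[base_pli$code == code]
        if (!length(it) || !length(ib))
          stop("missing PLI for ", ctry, "/", code)
        transfer_price(p0, it, ib)
      }, numeric(1))
      cost <- cost_of_basket(X, pp)
      rows[[length(rows) + 1]] <- data.frame(
        country = ctry, gender = fit$person$gender, percentile = q,
        cost_eur_day = cost, annual_cost_eur = cost * 365,
        income_share_pct = income_share(cost, incomes[[ctry]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(country = character(), gender = character(),
               percentile = numeric(), cost_eur_day = numeric(),
               annual_cost_eur = numeric(), income_share_pct = numeric())
  class(out) <- c("budget_table", "data.frame")
  out
}
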