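#' Aggregate food-group quantities into analysis categories
#'
#' @param quantities named g/day vector (profile quantities or \code{coef} of
#'   a fit).
#' @param registry a \code{food_registry} mapping every code to a category.
#' @return Named numeric vector over the ten categories (g/day); categories
#'   with no member groups present are 0.
#' @export
aggregate_categories <- function(quantities, registry) {
  idx <- match(names(quantities), registry$code)
  if (anyNA(idx))
    stop("group(s) not in registry: ",
         paste(names(quantities)[is.na(idx)], collapse = ", "))
  cats <- registry$category[idx]
  out <- stats::setNames(numeric(length(food_categories())), food_categories())
  agg <- tapply(quantities, cats, sum)
  out[names(agg)] <- agg
  out
}

#' Percentage change between observed and optimised quantity
#'
#' @param sC scaled observed quantity (g/day), > 0.
#' @param X optimised quantity (g/day).
#' @return (X - sC)/sC x 100; \code{NA} where sC is 0 (change undefined).
#' @export
percent_change <- function(sC, X) {
  ifelse(sC > 0, (X - sC) / sC * 100, NA_real_)
}

#' Cross-country correlation of observed and optimised consumption
#'
#' Pearson correlation across countries between observed (scaled) and
#' optimised quantities of one category, with two-sided significance at the
#' 5 \% and 1 \% levels from the exact t-transform with n-2 degrees of
#' freedom.  A positive, significant correlation indicates that
#' country-specific consumption preferences survive the optimisation.
#'
#' @param observed,optimised paired per-country vectors, length >= 3.
#' @return List: \code{r}, \code{p}, \code{sig5}, \code{sig1}, \code{n};
#'   \code{r} is \code{NA} with both flags \code{NA} if either vector has
#'   zero variance.
#' @export
cross_country_correlation <- function(observed, optimised) {
  if (length(observed) != length(optimised))
    stop("paired vectors must have equal length")
  n <- length(observed)
  if (n < 3) stop("need at least 3 countries")
  if (stats::sd(observed) == 0 || stats::sd(optimised) == 0)
    return(list(r = NA_real_, p = NA_real_, sig5 = NA, sig1 = NA, n = n))
  ct <- stats::cor.test(observed, optimised, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       sig5 = ct$p.value < 0.05, sig1 = ct$p.value < 0.01, n = n)
}

#' Classify countries against the angle bisector
#'
#' In an observed-versus-optimised scatter, a country above the bisector must
#' increase its consumption of the category to meet the recommendations; a
#' country below must decrease it.
#'
#' @param observed,optimised paired quantities (g/day).
#' @param tol absolute tolerance for "on" the bisector.
#' @return Character vector: \code{"above"}, \code{"below"} or \code{"on"}.
#' @export
bisector_classification <- function(observed, optimised, tol = 1e-8) {
  d <- optimised - observed
  ifelse(abs(d) <= tol, "on", ifelse(d > 0, "above", "below"))
}

#' Mean percentage changes and optimised quantities per category
#'
#' For each analysis category, first the percentage change between scaled
#' observed and optimised category totals is computed for every country
#' individually; then the cross-country mean of those changes is taken (the
#' mean of changes, deliberately not the change of means).  Mean optimised
#' quantities are cross-country means of the category totals.  Genders are
#' reported separately, never pooled.
#'
#' @param fits list of \code{diet_fit} objects (one gender).
#' @return data.frame: category, mean_change_pct, mean_optimised_g_day, n.
#' @export
change_summary <- function(fits) {
  fits <- Filter(function(f) f$status == "optimal", fits)
  if (!length(fits)) stop("no solved fits")
  per_cat <- lapply(fits, function(f) {
    sC_cat <- aggregate_categories(f$sC, f$registry)
    X_cat <- aggregate_categories(coef(f), f$registry)
    list(change = percent_change(sC_cat, X_cat), X = X_cat)
  })
  chg <- do.call(rbind, lapply(per_cat, `[[`, "change"))
  Xc <- do.call(rbind, lapply(per_cat, `[[`, "X"))
  data.frame(category = food_categories(),
             mean_change_pct = colMeans(chg, na.rm = TRUE),
             mean_optimised_g_day = colMeans(Xc),
             n = nrow(chg), row.names = NULL)
}

#' Cross-country correlation table per category
#'
#' @param fits list of \code{diet_fit} objects (one gender), length >= 3.
#' @return data.frame: category, r, p, sig5, sig1 (correlation of observed
#'   vs optimised category totals across countries).
#' @export
correlation_summary <- function(fits) {
  fits <- Filter(function(f) f$status == "optimal", fits)
  if (length(fits) < 3) stop("need fits for at least 3 countries")
  obs <- do.call(rbind, lapply(fits, function(f)
    aggregate_categories(f$sC, f$registry)))
  opt <- do.call(rbind, lapply(fits, function(f)
    aggregate_categories(coef(f), f$registry)))
  res <- lapply(food_categories(), function(cat_)
    cross_country_correlation(obs[, cat_], opt[, cat_]))
  data.frame(category = food_categories(),
             r = vapply(res, `[[`, 0, "r"),
             p = vapply(res, `[[`, 0, "p"),
             sig5 = vapply(res, `[[`, NA, "sig5"),
             sig1 = vapply(res, `[[`, NA, "sig1"),
             row.names = NULL)
}
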