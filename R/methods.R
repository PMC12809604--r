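#' @export
print.diet_fit <- function(x, ...) {
  cat(sprintf("Optimised healthy diet: %s (%s)\n", x$country, x$person$gender))
  if (x$status != "optimal") {
    cat("  status: infeasible at every floor tried (",
        nrow(x$trace), " attempts)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  food groups: %d   consumption floor: %.0f %%%s\n",
              length(x$coefficients), 100 * x$floor,
              if (nrow(x$trace) > 1)
                sprintf(" (relaxed in %d attempts)", nrow(x$trace)) else ""))
  cat(sprintf("  total departure of mean food intake (TDMI): %.4f\n", x$tdmi))
  cat(sprintf("  binding constraints: %d\n", length(x$binding)))
  invisible(x)
}

#' @export
coef.diet_fit <- function(object, ...) object$coefficients

#' @export
fitted.diet_fit <- function(object, ...) object$coefficients

#' Deviations of the optimised from the scaled observed diet
#'
#' @param object a \code{diet_fit}.
#' @param type \code{"absolute"} for X - sC in g/day, \code{"relative"} for
#'   (X - sC)/sC, the per-group contribution (unsigned) to TDMI.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.diet_fit <- function(object, type = c("absolute", "relative"), ...) {
  type <- match.arg(type)
  if (object$status != "optimal") stop("no solution: model infeasible")
  d <- object$coefficients - object$sC
  if (type == "relative") d <- d / object$sC
  d
}

#' @export
summary.diet_fit <- function(object, ...) {
  out <- list(fit = object)
  if (object$status == "optimal") {
    reg <- object$registry
    sC_cat <- aggregate_categories(object$sC, reg)
    X_cat <- aggregate_categories(object$coefficients, reg)
    out$categories <- data.frame(
      category = names(sC_cat),
      scaled_g_day = unname(sC_cat),
      optimised_g_day = unname(X_cat),
      change_pct = ifelse(sC_cat > 0,
                          (X_cat - sC_cat) / sC_cat * 100, NA_real_),
      row.names = NULL)
  }
  class(out) <- "summary.diet_fit"
  out
}

#' @export
print.summary.diet_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$categories)) {
    cat("\nCategory totals (g/day):\n")
    df <- x$categories
    df$scaled_g_day <- round(df$scaled_g_day, 1)
    df$optimised_g_day <- round(df$optimised_g_day, 1)
    df$change_pct <- round(df$change_pct, 1)
    print(df, row.names = FALSE)
    if (length(x$fit$binding)) {
      cat("\nBinding constraints:",
          paste(x$fit$binding, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Observed-versus-optimised scatter plot
#'
#' Plots scaled observed against optimised quantities per food group, with
#' the angle bisector: points above it are groups whose consumption must
#' increase to meet the recommendations, points below must decrease.
#'
#' @param x a \code{diet_fit}.
#' @param by_category colour points by analysis category.
#' @param ... passed to \code{plot}.
#' @export
plot.diet_fit <- function(x, by_category = TRUE, ...) {
  if (x$status != "optimal") stop("no solution to plot: model infeasible")
  sC <- x$sC; X <- x$coefficients
  cats <- x$registry$category[match(names(sC), x$registry$code)]
  col <- if (by_category)
    grDevices::hcl.colors(length(food_categories()), "Dark 3")[
      match(cats, food_categories())] else "black"
  lim <- range(0, sC, X)
  graphics::plot(sC, X, xlim = lim, ylim = lim, col = col, pch = 19,
                 xlab = "scaled observed consumption sC (g/day)",
                 ylab = "optimised consumption X (g/day)",
                 main = sprintf("%s (%s): observed vs optimised diet",
                                x$country, x$person$gender), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
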