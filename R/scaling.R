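#' Scale an observed diet to the recommended energy intake
#'
#' Observed mean energy intakes deviate from the recommended intake rE, so the
#' observed diet is anchored to rE before optimisation: every food-group
#' quantity is multiplied by the single factor rE/cE, which preserves the
#' percentage energy structure between the groups while making total energy
#' equal to the recommendation.  The scaled consumption sC is the starting
#' point of the optimisation.
#'
#' @param profile a \code{consumption_profile}.
#' @param nutrients a \code{nutrient_table} with an \code{energy} column.
#' @param person a \code{person_profile} supplying rE.
#' @return A \code{scaled_profile}: list with \code{country}, \code{gender},
#'   \code{quantities} (sC, g/day), \code{factor} (rE/cE), \code{rE_kcal},
#'   \code{cE_kcal}.
#' @export
scale_to_energy <- function(profile, nutrients, person) {
  stopifnot(inherits(profile, "consumption_profile"),
            inherits(person, "person_profile"))
  if (any(profile$quantities < 0)) stop("negative consumption quantity")
  cE <- profile_energy(profile, nutrients)
  if (cE <= 0) stop("observed diet has zero energy; nothing to scale")
  rE <- person$energy_kcal
  f <- rE / cE
  structure(list(country = profile$country, gender = person$gender,
                 quantities = profile$quantities * f,
                 factor = f, rE_kcal = rE, cE_kcal = cE,
                 absent = profile$absent),
            class = "scaled_profile")
}

#' @export
print.scaled_profile <- function(x, ...) {
  cat(sprintf("Scaled diet %s (%s): factor %.4f (cE %.0f -> rE %.0f kcal/day), %d groups\n",
              x$country, x$gender, x$factor, x$cE_kcal, x$rE_kcal,
              length(x$quantities)))
  invisible(x)
}
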