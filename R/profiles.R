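#' Reference person for diet optimisation
#'
#' The adult reference individuals the diet model is solved for: 25-49 years,
#' sedentary activity (PAL 1.4).  Defaults follow the standard assumptions for
#' this age band: a man of 82 kg with a recommended energy intake of 9.4
#' MJ/day and a woman of 66 kg with 7.55 MJ/day.
#'
#' @param gender \code{"man"} or \code{"woman"}.
#' @param bodyweight_kg body weight in kg.
#' @param pal physical activity level (dimensionless).
#' @param energy_mj recommended daily energy intake in MJ.
#' @return A \code{person_profile} list with fields \code{gender},
#'   \code{bodyweight_kg}, \code{pal}, \code{energy_mj}, \code{energy_kcal}
#'   and \code{age_band}.
#' @export
person_profile <- function(gender = c("man", "woman"),
                           bodyweight_kg = NULL, pal = 1.4,
                           energy_mj = NULL) {
  gender <- match.arg(gender)
  defaults <- list(man = list(bw = 82, mj = 9.4),
                   woman = list(bw = 66, mj = 7.55))[[gender]]
  if (is.null(bodyweight_kg)) bodyweight_kg <- defaults$bw
  if (is.null(energy_mj)) energy_mj <- defaults$mj
  if (bodyweight_kg <= 0) stop("body weight must be positive")
  if (energy_mj <= 0) stop("recommended energy intake must be positive")
  structure(list(gender = gender, age_band = "25-49",
                 bodyweight_kg = bodyweight_kg, pal = pal,
                 energy_mj = energy_mj,
                 energy_kcal = energy_mj * 1000 / KJ_PER_KCAL),
            class = "person_profile")
}

#' @export
print.person_profile <- function(x, ...) {
  cat(sprintf("Reference person: %s, %s y, %.0f kg, PAL %.1f, %.2f MJ/day (%.0f kcal)\n",
              x$gender, x$age_band, x$bodyweight_kg, x$pal, x$energy_mj,
              x$energy_kcal))
  invisible(x)
}

#' Construct a consumption profile
#'
#' An observed mean at-home diet of one country (optionally gender-specific):
#' grams per person per day for each food group.  Groups without a consumption
#' record are absent from the vector, not zero -- an absent group drops out of
#' the model dimension entirely, mirroring how a survey gap is handled.
#'
#' @param country country code.
#' @param quantities named numeric vector, food-group code -> g/day.
#' @param gender \code{"man"}, \code{"woman"} or \code{NA} (shared diet).
#' @param absent codes known to the registry but missing from the data.
#' @return A \code{consumption_profile}.
#' @export
consumption_profile <- function(country, quantities, gender = NA_character_,
                                absent = character()) {
  if (is.null(names(quantities)) || any(!nzchar(names(quantities))))
    stop("quantities must be named by food-group code")
  if (any(quantities < 0))
    stop("negative consumption for group(s): ",
         paste(names(quantities)[quantities < 0], collapse = ", "))
  structure(list(country = as.character(country), gender = gender,
                 quantities = quantities, absent = absent),
            class = "consumption_profile")
}

#' Energy content of a consumption profile
#'
#' Observed mean energy intake cE: sum over groups of quantity/100 times the
#' group's energy per 100 g.
#'
#' @param profile a \code{consumption_profile} (or named g/day vector).
#' @param nutrients a \code{nutrient_table} with an \code{energy} column.
#' @return Energy in kcal/day.
#' @export
profile_energy <- function(profile, nutrients) {
  q <- if (inherits(profile, "consumption_profile")) profile$quantities else profile
  miss <- setdiff(names(q), rownames(nutrients))
  if (length(miss))
    stop("no nutrient record for group(s): ", paste(miss, collapse = ", "))
  sum(q / 100 * nutrients[names(q), "energy"])
}

#' @export
print.consumption_profile <- function(x, ...) {
  cat(sprintf("Consumption profile %s%s: %d food groups, %.0f g/day total",
              x$country,
              if (is.na(x$gender)) "" else paste0(" (", x$gender, ")"),
              length(x$quantities), sum(x$quantities)))
  if (length(x$absent)) cat(sprintf(", %d absent", length(x$absent)))
  cat("\n")
  invisible(x)
}

#' Read consumption profiles from CSV
#'
#' Expected columns: \code{country}, \code{code}, \code{quantity_g_day} and
#' optionally \code{gender}.  One profile is built per country (per
#' country-gender pair when the gender column is present).  Codes are
#' validated against the registry; registry groups missing from a country's
#' rows are recorded as absent on that profile and reported via a message.
#'
#' @param path CSV file.
#' @param registry a \code{food_registry} to validate codes against.
#' @return List of \code{consumption_profile} objects.
#' @export
read_consumption <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  need <- c("country", "code", "quantity_g_day")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("consumption file lacks column(s): ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(unique(df$code), registry$code)
  if (length(unknown))
    stop("unknown food-group code(s): ", paste(unknown, collapse = ", "))
  neg <- which(df$quantity_g_day < 0)
  if (length(neg))
    stop("negative quantity in row(s): ", paste(neg, collapse = ", "))
  if (!"gender" %in% names(df)) df$gender <- NA_character_
  df$gender[df$gender %in% c("", "NA")] <- NA_character_
  key <- paste(df$country, ifelse(is.na(df$gender), "", df$gender))
  profiles <- lapply(split(df, factor(key, levels = unique(sort(key)))),
                     function(d) {
    q <- stats::setNames(d$quantity_g_day, d$code)
    if (anyDuplicated(names(q)))
      stop("duplicate rows for country ", d$country[1], " code(s): ",
           paste(names(q)[duplicated(names(q))], collapse = ", "))
    q <- q[order(names(q), method = "radix")]
    absent <- setdiff(registry$code, names(q))
    if (length(absent))
      message("country ", d$country[1], ": no consumption record for ",
              length(absent), " group(s): ", paste(absent, collapse = ", "))
    consumption_profile(d$country[1], q, gender = d$gender[1], absent = absent)
  })
  unname(profiles)
}

#' Write consumption profiles to CSV
#' @param profiles list of \code{consumption_profile}
#' @param path output CSV
#' @return \code{path}, invisibly.
#' @export
write_consumption <- function(profiles, path) {
  if (inherits(profiles, "consumption_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(country = p$country, gender = p$gender,
               code = names(p$quantities),
               quantity_g_day = unname(p$quantities),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
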