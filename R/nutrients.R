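#' Canonical nutrient units
#'
#' The per-100 g unit in which each nutrient is stored internally.  Energy is
#' kept in kcal; macronutrients, water and salt in g; cholesterol and the
#' milligram micronutrients in mg; vitamin D in micrograms.  Constraint values
#' arriving in \code{g/day}, \code{mg/day} or \code{ug/day} must agree with the
#' target nutrient's canonical unit.
#'
#' @return Named character vector, nutrient key -> unit.
#' @export
nutrient_units <- function() {
  c(energy = "kcal", protein = "g", fat = "g", satfat = "g", pufa = "g",
    cholesterol = "mg", carbohydrate = "g", free_sugars = "g", fibre = "g",
    water = "g", salt = "g",
    thiamin = "mg", vitamin_c = "mg", vitamin_d = "ug",
    calcium = "mg", iron = "mg")
}

#' Energy conversion factors of energy-providing nutrients (kJ per g)
#'
#' Fixed to the EC Directive 90/496/EEC nutrition-labelling values.  Free
#' sugars convert with the carbohydrate factor.
#'
#' @return Named numeric vector of kJ/g factors.
#' @export
energy_factors_kj <- function() {
  c(protein = 17, carbohydrate = 17, free_sugars = 17, fat = 37,
    satfat = 37, pufa = 37, fibre = 8, alcohol = 29)
}

#' kJ per kcal
#' @export
KJ_PER_KCAL <- 4.184

#' Build a nutrient composition table
#'
#' Assembles and validates the per-100 g nutrient contents of every food
#' group.  Two soft checks mirror what a curated composition database should
#' satisfy: the mass of water plus macronutrients must not exceed 100 g per
#' 100 g, and the declared energy should be consistent with the
#' energy-providing nutrients under the declared energy factors.  Both emit
#' warnings, not errors, because survey-aggregated composition data routinely
#' carries small inconsistencies.
#'
#' @param mat numeric matrix, rows = food-group codes, columns = nutrient
#'   keys; contents per 100 g in canonical units.
#' @param mass_tol tolerance (g) on the water + macronutrient mass check.
#' @param energy_tol relative tolerance on the energy consistency check.
#' @return The validated matrix with class \code{nutrient_table}.
#' @export
nutrient_table <- function(mat, mass_tol = 1.0, energy_tol = 0.05) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("nutrient table needs food-group codes as rownames and nutrient keys as colnames")
  if (any(mat < 0, na.rm = TRUE))
    stop("negative nutrient content for group(s): ",
         paste(rownames(mat)[apply(mat < 0, 1, any)], collapse = ", "))
  mass_cols <- intersect(c("protein", "fat", "carbohydrate", "fibre",
                           "water", "salt"), colnames(mat))
  mass <- rowSums(mat[, mass_cols, drop = FALSE])
  if (any(mass > 100 + mass_tol))
    warning("water + macronutrient mass exceeds 100 g/100 g for: ",
            paste(rownames(mat)[mass > 100 + mass_tol], collapse = ", "))
  if ("energy" %in% colnames(mat)) {
    fk <- energy_factors_kj()
    en_cols <- intersect(c("protein", "carbohydrate", "fat", "fibre"),
                         colnames(mat))
    pred <- as.vector(mat[, en_cols, drop = FALSE] %*% fk[en_cols]) / KJ_PER_KCAL
    rel <- abs(pred - mat[, "energy"]) / pmax(mat[, "energy"], 1)
    if (any(rel > energy_tol))
      warning("declared energy deviates from energy-factor computation for: ",
              paste(rownames(mat)[rel > energy_tol], collapse = ", "))
  }
  class(mat) <- c("nutrient_table", class(mat))
  mat
}

#' Read a nutrient composition table from long-format CSV
#'
#' Expected columns: \code{code}, \code{nutrient}, \code{per100g},
#' \code{unit}.  Units are checked against the canonical unit registry;
#' nutrient keys outside the registry are kept (micronutrient map is open)
#' but their units are taken at face value.
#'
#' @param path CSV file.
#' @inheritParams nutrient_table
#' @return A \code{nutrient_table}.
#' @export
read_nutrients <- function(path, mass_tol = 1.0, energy_tol = 0.05) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "nutrient", "per100g", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("nutrient file lacks column(s): ",
                         paste(miss, collapse = ", "))
  units <- nutrient_units()
  known <- df$nutrient %in% names(units)
  bad <- known & df$unit != units[df$nutrient]
  if (any(bad))
    stop("unit mismatch for nutrient(s): ",
         paste(unique(df$nutrient[bad]), collapse = ", "),
         " (expected ", paste(unique(units[df$nutrient[bad]]), collapse = ", "), ")")
  codes <- sort(unique(df$code), method = "radix")
  keys <- unique(df$nutrient)
  mat <- matrix(0, nrow = length(codes), ncol = length(keys),
                dimnames = list(codes, keys))
  mat[cbind(match(df$code, codes), match(df$nutrient, keys))] <- df$per100g
  nutrient_table(mat, mass_tol = mass_tol, energy_tol = energy_tol)
}

#' Write a nutrient table to long-format CSV
#' @param nutrients a \code{nutrient_table}
#' @param path output CSV
#' @return \code{path}, invisibly.
#' @export
write_nutrients <- function(nutrients, path) {
  units <- nutrient_units()
  df <- data.frame(
    code = rep(rownames(nutrients), ncol(nutrients)),
    nutrient = rep(colnames(nutrients), each = nrow(nutrients)),
    per100g = as.vector(nutrients),
    unit = rep(ifelse(colnames(nutrients) %in% names(units),
                      units[colnames(nutrients)], ""), each = nrow(nutrients)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
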