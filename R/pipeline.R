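#' Run the full Food Reference Budget pipeline
#'
#' Orchestrates scale -> constrain -> solve -> price -> analyse for every
#' country and reference person: each observed diet is scaled to the
#' recommended energy intake, optimised under the recommendation bounds with
#' the floor-relaxation loop, priced at the requested lower price percentiles
#' with PLI transfer from the base country, and summarised.  Countries are
#' processed independently; a per-country solve failure is recorded and the
#' run continues.  The returned manifest (input checksums, parameters, floors
#' used) fully determines the outputs.
#'
#' @param bundle either a bundle list from \code{synth_generate} or a list
#'   with the same elements built from files (\code{registry},
#'   \code{nutrients}, \code{profiles}, \code{prices}, \code{pli},
#'   \code{incomes}, \code{base_country}, \code{constraints}).
#' @param genders persons to run (\code{"man"}, \code{"woman"}).
#' @param floor,step,min_floor floor-relaxation parameters.
#' @param percentiles ascending price percentiles in (0, 100).
#' @param allowance optional daily food allowance (EUR/day) benchmarked
#'   against the base country's percentile costs.
#' @return An \code{frb_run} list: \code{fits}, \code{budgets},
#'   \code{changes} (per gender), \code{correlations} (per gender, when >= 3
#'   countries solved), \code{benchmark} (per gender, if \code{allowance}),
#'   \code{manifest}.
#' @export
frb_run <- function(bundle, genders = c("man", "woman"),
                    floor = 0.10, step = 0.01, min_floor = 0,
                    percentiles = c(20, 30, 40, 50), allowance = NULL) {
  stopifnot(all(genders %in% c("man", "woman")))
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie in (0, 100)")
  if (is.unsorted(percentiles)) stop("percentiles must be ascending")
  # cross-file consistency before any solve
  prof_codes <- unique(unlist(lapply(bundle$profiles,
                                     function(p) names(p$quantities))))
  bad <- setdiff(prof_codes, rownames(bundle$nutrients))
  if (length(bad))
    stop("consumption/nutrient code mismatch: ", paste(bad, collapse = ", "))
  bad <- setdiff(prof_codes, bundle$registry$code)
  if (length(bad))
    stop("consumption/registry code mismatch: ", paste(bad, collapse = ", "))

  fits <- list()
  failures <- list()
  for (g in genders) {
    person <- person_profile(g)
    profs <- Filter(function(p) is.na(p$gender) || p$gender == g,
                    bundle$profiles)
    for (p in profs) {
      fit <- tryCatch(
        fit_diet(p, bundle$nutrients, bundle$constraints, person,
                 bundle$registry, floor = floor, step = step,
                 min_floor = min_floor),
        error = function(e) e)
      key <- paste(p$country, g, sep = ".")
      if (inherits(fit, "error") ||
          (inherits(fit, "diet_fit") && fit$status != "optimal")) {
        failures[[key]] <- if (inherits(fit, "error")) conditionMessage(fit)
                           else "infeasible"
        if (inherits(fit, "diet_fit")) fits[[key]] <- fit
      } else fits[[key]] <- fit
    }
  }
  solved <- Filter(function(f) f$status == "optimal", fits)
  budgets <- budget_table(solved, bundle$prices, bundle$pli, bundle$incomes,
                          bundle$base_country, percentiles = percentiles)
  changes <- list(); correlations <- list(); benchmark <- list()
  for (g in genders) {
    gf <- Filter(function(f) f$person$gender == g, solved)
    if (length(gf)) changes[[g]] <- change_summary(gf)
    if (length(gf) >= 3) correlations[[g]] <- correlation_summary(gf)
    if (!is.null(allowance)) {
      bc <- budgets[budgets$country == bundle$base_country &
                      budgets$gender == g, ]
      if (nrow(bc))
        benchmark[[g]] <- benchmark_against_allowance(
          stats::setNames(bc$cost_eur_day, bc$percentile), allowance)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("frbudget")),
    inputs = bundle_checksums(bundle),
    parameters = list(genders = genders, floor = floor, step = step,
                      min_floor = min_floor, percentiles = percentiles,
                      allowance = allowance),
    floors_used = lapply(fits, function(f) f$floor),
    failures = failures)
  structure(list(fits = fits, budgets = budgets, changes = changes,
                 correlations = correlations, benchmark = benchmark,
                 manifest = manifest),
            class = "frb_run")
}

# md5 checksums of the bundle's components via their serialized form
bundle_checksums <- function(bundle) {
  parts <- c("registry", "nutrients", "profiles", "prices", "pli",
             "incomes", "constraints")
  out <- list()
  for (p in parts) {
    if (is.null(bundle[[p]])) next
    tf <- tempfile()
    saveRDS(bundle[[p]], tf, version = 2, compress = FALSE)
    out[[p]] <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  out
}

#' @export
print.frb_run <- function(x, ...) {
  solved <- sum(vapply(x$fits, function(f) f$status == "optimal", TRUE))
  cat("Food Reference Budget run\n")
  cat(sprintf("  diets solved: %d of %d\n", solved, length(x$fits)))
  cat(sprintf("  budget rows: %d (percentiles %s)\n", nrow(x$budgets),
              paste(x$manifest$parameters$percentiles, collapse = "/")))
  if (length(x$manifest$failures))
    cat("  failures:", paste(names(x$manifest$failures), collapse = ", "),
        "\n")
  if (nrow(x$budgets)) {
    r <- range(x$budgets$cost_eur_day[x$budgets$percentile ==
                                        min(x$budgets$percentile)])
    cat(sprintf("  cost range at %dth percentile: %.2f - %.2f EUR/day\n",
                min(x$budgets$percentile), r[1], r[2]))
  }
  invisible(x)
}

#' Write the outputs of a pipeline run to a directory
#'
#' @param run an \code{frb_run}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$budgets, file.path(dir, "budgets.csv"),
                   row.names = FALSE)
  for (g in names(run$changes))
    utils::write.csv(run$changes[[g]],
                     file.path(dir, paste0("changes_", g, ".csv")),
                     row.names = FALSE)
  for (g in names(run$correlations))
    utils::write.csv(run$correlations[[g]],
                     file.path(dir, paste0("correlations_", g, ".csv")),
                     row.names = FALSE)
  for (key in names(run$fits))
    if (run$fits[[key]]$status == "optimal")
      write_solution(run$fits[[key]],
                     file.path(dir, paste0("solution_", key, ".csv")))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
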