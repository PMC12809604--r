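#' Write a solved diet to CSV
#'
#' Per-group rows (code, name, category, scaled and optimised g/day, percent
#' change) preceded by comment header lines recording the country, gender,
#' floor used, TDMI and solver status, so the file is self-describing and
#' re-readable.
#'
#' @param fit a solved \code{diet_fit}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_solution <- function(fit, path) {
  stopifnot(inherits(fit, "diet_fit"))
  if (fit$status != "optimal") stop("cannot write an unsolved solution")
  if (!length(fit$coefficients)) stop("solution has an empty group set")
  reg <- fit$registry
  idx <- match(names(fit$sC), reg$code)
  df <- data.frame(code = names(fit$sC),
                   name = reg$name[idx],
                   category = reg$category[idx],
                   scaled_g_day = unname(fit$sC),
                   optimised_g_day = unname(fit$coefficients),
                   change_pct = unname(percent_change(fit$sC,
                                                      fit$coefficients)),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# country: %s", fit$country),
               sprintf("# gender: %s", fit$person$gender),
               sprintf("# floor_pct: %.15g", 100 * fit$floor),
               sprintf("# tdmi: %.15g", fit$tdmi),
               sprintf("# status: %s", fit$status)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a written diet solution
#'
#' @param path CSV produced by \code{write_solution}.
#' @return List: \code{header} (country, gender, floor, tdmi, status) and
#'   \code{table} (the per-group data.frame).
#' @export
read_solution <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *([^:]+): *(.*)$", "\\1\t\\2", hdr)
  parts <- strsplit(kv, "\t")
  header <- stats::setNames(lapply(parts, `[`, 2),
                            vapply(parts, `[`, "", 1))
  for (k in c("floor_pct", "tdmi"))
    if (!is.null(header[[k]])) header[[k]] <- as.numeric(header[[k]])
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                        stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  list(header = header, table = df)
}
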