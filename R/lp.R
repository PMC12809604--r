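#' Total departure of mean food intake (TDMI)
#'
#' The objective the diet optimisation minimises: the sum over food groups of
#' the absolute difference between optimised and scaled observed quantities,
#' standardised by the scaled observed quantity, TDMI = sum_i |X_i - sC_i| /
#' sC_i.  Division by sC_i makes departures comparable between large and
#' small food groups.
#'
#' @param X optimised quantities, g/day.
#' @param sC scaled observed quantities, g/day; all strictly positive.
#' @return Nonnegative number.
#' @export
tdmi <- function(X, sC) {
  if (length(X) != length(sC)) stop("X and sC must have the same length")
  if (any(sC <= 0))
    stop("sC contains nonpositive quantities; zero-consumption groups must be dropped upstream")
  sum(abs(X - sC) / sC)
}

#' Linearize the TDMI objective into an LP model
#'
#' The absolute-value objective is transformed into a linear programme with
#' paired nonnegative deviation variables, the standard goal-programming
#' construction: X_i = sC_i (1 + p_i - q_i), minimise sum_i (p_i + q_i).
#' At any optimum p_i and q_i cannot both be positive (both carry positive
#' cost), so the objective equals TDMI.  Consumption floors X_i >= floor x
#' sC_i keep every consumed food group in the basket; the assembled
#' recommendation bounds act on X.
#'
#' @param sC named vector of scaled quantities, all > 0.
#' @param bounds list of \code{linear_bound}s.
#' @param floor consumption floor as a fraction of sC, in [0, 1).
#' @return An \code{lp_model}: variable order is (X_1..n, p_1..n, q_1..n).
#' @export
linearize <- function(sC, bounds, floor = 0.10) {
  n <- length(sC)
  if (n == 0) stop("empty food-group set")
  if (any(sC <= 0)) stop("sC must be strictly positive")
  if (floor < 0 || floor >= 1) stop("floor must be in [0, 1)")
  codes <- names(sC)
  obj <- c(rep(0, n), rep(1, 2 * n))
  # identities X_i - sC_i p_i + sC_i q_i = sC_i
  A3 <- cbind(diag(n), -diag(sC, n), diag(sC, n))
  b3 <- unname(sC)
  # floors
  A2 <- cbind(diag(n), matrix(0, n, 2 * n))
  b2 <- unname(floor * sC)
  r2_id <- paste0("floor:", codes)
  A1 <- NULL; b1 <- numeric(); r1_id <- character()
  for (b in bounds) {
    row <- numeric(3 * n)
    common <- intersect(names(b$coef), codes)
    row[match(common, codes)] <- b$coef[common]
    if (b$rhs < 0) stop("negative RHS in bound ", b$id)
    if (b$dir == "<=") {
      A1 <- rbind(A1, row); b1 <- c(b1, b$rhs); r1_id <- c(r1_id, b$id)
    } else if (b$dir == ">=") {
      A2 <- rbind(A2, row); b2 <- c(b2, b$rhs); r2_id <- c(r2_id, b$id)
    } else {
      A3 <- rbind(A3, row); b3 <- c(b3, b$rhs)
    }
  }
  structure(list(codes = codes, sC = sC, obj = obj,
                 A1 = A1, b1 = b1, r1_id = r1_id,
                 A2 = A2, b2 = b2, r2_id = r2_id,
                 A3 = A3, b3 = b3, floor = floor, n = n,
                 n_var = 3 * n, bounds = bounds),
            class = "lp_model")
}

#' Solve a linearized diet model
#'
#' Solves the LP with a deterministic dense two-phase simplex
#' (\code{boot::simplex}), so repeated solves of the same model are
#' bit-identical.  As a presolve step the identity rows X_i = sC_i (1 + p_i -
#' q_i) are eliminated by substitution, so the simplex works on the deviation
#' variables only (2n instead of 3n) with the consumption floors reduced to
#' simple caps q_i <= 1 - floor; this removes every equality artificial and
#' with it the degeneracy a dense phase-1 handles poorly.  Constraints whose
#' slack at the optimum is below \code{binding_tol} are reported as binding.
#'
#' @param model an \code{lp_model}.
#' @param binding_tol absolute slack below which a bound counts as binding.
#' @param n_iter simplex iteration cap.
#' @return A \code{diet_solution}: list with \code{status}
#'   (\code{"optimal"}/\code{"infeasible"}), \code{X}, \code{objective},
#'   \code{binding}, \code{floor}.
#' @export
solve_diet_lp <- function(model, binding_tol = 1e-7, n_iter = 50000) {
  stopifnot(inherits(model, "lp_model"))
  n <- model$n
  sC <- unname(model$sC)
  A1 <- NULL; b1 <- numeric(); A2 <- NULL; b2 <- numeric()
  A3 <- NULL; b3 <- numeric()
  add <- function(row, dir, rhs) {
    if (rhs < 0) {  # boot::simplex requires nonnegative RHS
      row <- -row; rhs <- -rhs
      dir <- c("<=" = ">=", ">=" = "<=", "=" = "=")[[dir]]
    }
    if (dir == "<=") { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
    else if (dir == ">=") { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
    else { A3 <<- rbind(A3, row); b3 <<- c(b3, rhs) }
  }
  for (b in model$bounds) {
    av <- numeric(n)
    common <- intersect(names(b$coef), model$codes)
    av[match(common, model$codes)] <- b$coef[common]
    w <- av * sC
    add(c(w, -w), b$dir, b$rhs - sum(w))
  }
  for (i in seq_len(n)) {
    row <- numeric(2 * n); row[n + i] <- 1
    add(row, "<=", 1 - model$floor)
  }
  s <- boot::simplex(a = rep(1, 2 * n), A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                     A3 = A3, b3 = b3, maxi = FALSE, n.iter = n_iter)
  if (s$solved == -1)
    return(structure(list(status = "infeasible", X = NULL, objective = NA_real_,
                          binding = character(), floor = model$floor),
                     class = "diet_solution"))
  if (s$solved != 1)
    stop("LP solver failed (iteration limit); solver state: solved = ", s$solved)
  p <- s$soln[seq_len(n)]
  q <- s$soln[n + seq_len(n)]
  X <- stats::setNames(pmax(sC * (1 + p - q), 0), model$codes)
  obj <- max(unname(s$value), 0)  # clamp solver float noise
  dev <- tdmi(X, model$sC)
  if (abs(obj - dev) > 1e-6 * max(1, dev))
    stop("solver objective ", obj, " disagrees with TDMI ", dev)
  binding <- character()
  chk <- check_bounds(X, model$bounds, tol = 1e-6)
  slack <- attr(chk, "slack")
  binding <- names(slack)[abs(slack) <= binding_tol]
  floor_slack <- X - model$floor * model$sC
  binding <- c(binding,
               paste0("floor:", model$codes[abs(floor_slack) <= binding_tol]))
  structure(list(status = "optimal", X = X, objective = obj,
                 binding = binding, floor = model$floor),
            class = "diet_solution")
}

#' Solve with stepwise floor relaxation
#'
#' An observed diet far from the recommendations can make the model
#' infeasible at the default 10 \% consumption floor.  Following the standard
#' handling, the floor is lowered in 1 \% steps until the model solves (or
#' \code{min_floor} is passed); each attempt is logged.
#'
#' @param sC named scaled quantities, all > 0.
#' @param bounds list of \code{linear_bound}s.
#' @param start_floor starting floor (default 0.10).
#' @param step reduction per attempt (default 0.01); must be > 0.
#' @param min_floor lowest floor tried (default 0).
#' @return A \code{diet_solution} with an extra \code{trace} data.frame
#'   (columns \code{floor}, \code{status}); status \code{"infeasible"} with
#'   the full trace if no floor works.
#' @export
solve_with_relaxation <- function(sC, bounds, start_floor = 0.10,
                                  step = 0.01, min_floor = 0) {
  if (step <= 0) stop("step must be positive")
  floors <- seq(start_floor, min_floor, by = -step)
  if (!length(floors)) floors <- start_floor
  trace <- data.frame(floor = numeric(), status = character())
  for (f in floors) {
    sol <- solve_diet_lp(linearize(sC, bounds, floor = f))
    trace <- rbind(trace, data.frame(floor = f, status = sol$status))
    if (sol$status == "optimal") {
      sol$trace <- trace
      return(sol)
    }
  }
  structure(list(status = "infeasible", X = NULL, objective = NA_real_,
                 binding = character(), floor = NA_real_, trace = trace),
            class = "diet_solution")
}

#' Fit the closest healthy diet to an observed one
#'
#' The package's central fitting function.  The observed diet is scaled to
#' the person's recommended energy intake, the recommendation set is
#' converted to gram-space bounds, and the goal-programming LP finds the
#' diet satisfying every bound while minimising the total departure of mean
#' food intake (TDMI) from the scaled diet.  Food groups the country does
#' not consume are dropped from the model dimension (a floor cannot apply to
#' them and the relative departure is undefined).
#'
#' @param profile a \code{consumption_profile} (observed diet, g/day).
#' @param nutrients a \code{nutrient_table}.
#' @param constraints a \code{constraint_set} (or list of
#'   \code{constraint_spec}s).
#' @param person a \code{person_profile}; defaults to the reference man.
#' @param registry a \code{food_registry} for resolving food-based rules.
#' @param floor,step,min_floor floor-relaxation parameters (fractions).
#' @return A \code{diet_fit} object with methods \code{print}, \code{summary},
#'   \code{coef}, \code{fitted}, \code{residuals} and \code{plot}.
#' @examples
#' reg <- default_registry()
#' synth <- synth_generate(synth_config(n_countries = 1, seed = 7))
#' fit <- fit_diet(synth$profiles[[1]], synth$nutrients, synth$constraints,
#'                 person_profile("man"), reg)
#' fit
#' @export
fit_diet <- function(profile, nutrients, constraints,
                     person = person_profile("man"), registry = NULL,
                     floor = 0.10, step = 0.01, min_floor = 0) {
  stopifnot(inherits(profile, "consumption_profile"))
  if (is.null(registry)) registry <- default_registry()
  sp <- scale_to_energy(profile, nutrients, person)
  sC <- sp$quantities[sp$quantities > 0]
  dropped <- setdiff(names(sp$quantities), names(sC))
  nut <- nutrients[intersect(rownames(nutrients), names(sC)), , drop = FALSE]
  miss <- setdiff(names(sC), rownames(nutrients))
  if (length(miss))
    stop("no nutrient record for consumed group(s): ",
         paste(miss, collapse = ", "))
  reg <- registry[registry$code %in% names(sC), , drop = FALSE]
  bounds <- assemble_constraints(constraints, reg, nut, person)
  sol <- solve_with_relaxation(sC, bounds, start_floor = floor,
                               step = step, min_floor = min_floor)
  structure(list(country = profile$country, person = person,
                 coefficients = sol$X, sC = sC, scale_factor = sp$factor,
                 cE_kcal = sp$cE_kcal, rE_kcal = sp$rE_kcal,
                 tdmi = sol$objective, floor = sol$floor,
                 status = sol$status, binding = sol$binding,
                 trace = sol$trace, bounds = bounds,
                 dropped = c(dropped, profile$absent),
                 registry = registry),
            class = "diet_fit")
}
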