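#' Relative deviation of an optimised food weight from its baseline
#'
#' \eqn{RD = (w_{opt} - w_{rep}) / w_{rep}}: 0 means unchanged, -1 removal,
#' +2 the tripling bound. Defined only for foods with positive baseline
#' intake (foods absent from the baseline are not decision variables).
#'
#' @param w_opt,w_rep Numeric vectors of optimised and reported weights
#'   (g/day), recycled to a common length.
#' @return Numeric vector of relative deviations (dimensionless).
#' @export
relative_deviation <- function(w_opt, w_rep) {
  if (any(w_rep <= 0)) {
    abort("relative_deviation requires w_rep > 0 for every food",
          class = "dietshift_validation_error")
  }
  (w_opt - w_rep) / w_rep
}

#' Build the minimum-total-relative-deviation linear programme
#'
#' Decision variables are the optimised food weights, re-parameterised as
#' \eqn{w_{opt,i} = w_{rep,i}(1 + d^+_i - d^-_i)} with deviation splits
#' \eqn{d^+_i, d^-_i \ge 0}; the objective minimises
#' \eqn{\sum_i (d^+_i + d^-_i)}, the linearisation of the total relative
#' deviation \eqn{\sum_i |RD_i|}. Constraints:
#' * energy equality: optimised dietary energy equals baseline energy;
#' * one row per nutrient bound in `spec$drv_table`, with sex-specific limits
#'   weighted by the baseline's sex counts and percent-of-energy limits
#'   converted against the (fixed) baseline energy via Atwater factors;
#' * the four food-based dietary guidelines (fractional category memberships;
#'   the whole-grain limit is scaled as 75 g per 10 MJ of baseline energy);
#' * optionally a cap on total CO2eq;
#' * bounds: every food may fall to 0 (\eqn{d^- \le 1}); non-exempt foods may
#'   rise at most `max_increase_rd`-fold relative (+200 % by default), exempt
#'   groups have no upper bound.
#'
#' @param baseline A [baseline_diet()].
#' @param foods Composition tibble (as in a [survey_population()]).
#' @param spec A [diet_model_spec()].
#' @return An object of class `diet_lp_model`.
#' @export
build_model <- function(baseline, foods, spec) {
  stopifnot(inherits(baseline, "baseline_diet"),
            inherits(spec, "diet_model_spec"))
  if (nrow(baseline$weights) == 0) {
    abort("Baseline diet is empty", class = "dietshift_validation_error")
  }
  fd <- baseline$weights |>
    inner_join(foods, by = "food_id")
  if (nrow(fd) != nrow(baseline$weights)) {
    abort("Baseline refers to foods absent from the composition table",
          class = "dietshift_validation_error")
  }
  w_rep <- fd$w_rep
  e0 <- baseline$energy_kcal
  nf <- baseline$sex_counts[["n_female"]]
  nm <- baseline$sex_counts[["n_male"]]
  sex_weight <- function(lf, lm) {
    if (nf + nm == 0) (lf + lm) / 2 else (nf * lf + nm * lm) / (nf + nm)
  }

  ids <- character(0); dirs <- character(0); lims <- numeric(0)
  C <- matrix(0, nrow = 0, ncol = nrow(fd))

  add_row <- function(id, dir, lim, coef) {
    ids <<- c(ids, id); dirs <<- c(dirs, dir); lims <<- c(lims, lim)
    C <<- rbind(C, coef)
  }

  add_row("energy", "eq", e0, fd$energy_kcal_per_g)

  if (isTRUE(spec$use_drv)) {
    for (r in seq_len(nrow(spec$drv_table))) {
      row <- spec$drv_table[r, ]
      nut <- row$nutrient_id
      if (!nut %in% names(fd)) {
        abort(paste0("DRV constraint on '", nut,
                     "' but composition has no such nutrient column"),
              class = "dietshift_schema_error")
      }
      lim <- sex_weight(row$limit_female, row$limit_male)
      if (row$basis == "percent_energy") {
        atw <- ATWATER_KCAL_PER_G[[nut]]
        if (is.null(atw) || is.na(atw)) {
          abort(paste0("No energy conversion factor for nutrient '", nut, "'"),
                class = "dietshift_schema_error")
        }
        lim <- lim / 100 * e0 / atw
      }
      add_row(paste0("drv_", nut, "_", row$kind),
              if (row$kind == "lower") "ge" else "le", lim, fd[[nut]])
    }
  }

  if (isTRUE(spec$use_fbdg)) {
    coef_of <- c(fruit_veg = "fv_frac", seafood = "seafood_frac",
                 whole_grains = "whole_grain_frac",
                 red_processed_meat = "rpm_frac")
    for (r in seq_len(nrow(spec$fbdg_table))) {
      row <- spec$fbdg_table[r, ]
      lim <- row$limit
      if (row$basis == "per_10MJ") lim <- lim * kcal_to_mj(e0) / 10
      add_row(paste0("fbdg_", row$category),
              if (row$direction == "ge") "ge" else "le",
              lim, fd[[coef_of[[row$category]]]])
    }
  }

  if (!is.null(spec$co2eq_cap_g)) {
    add_row("co2eq_cap", "le", spec$co2eq_cap_g, fd$co2eq_g_per_g)
  }

  rownames(C) <- ids
  structure(
    list(food_ids = fd$food_id, foods = fd, w_rep = w_rep,
         energy_kcal = e0,
         constraints = tibble(id = ids, direction = dirs, limit = lims),
         C = C, exempt = fd$exempt, max_increase_rd = spec$max_increase_rd,
         sex_counts = baseline$sex_counts, spec = spec),
    class = "diet_lp_model"
  )
}

# Restrict a model to a subset of its constraint rows (bounds always kept);
# used by the feasibility probe's witness search.
subset_model <- function(model, keep_ids) {
  keep <- model$constraints$id %in% keep_ids
  model$constraints <- model$constraints[keep, ]
  model$C <- model$C[keep, , drop = FALSE]
  model
}

# Translate the w-space model into the d-space tableau and run the two-phase
# simplex from boot. Rows with negative right-hand side are flipped because
# the backend requires nonnegative constants. Rows are passed unscaled: the
# backend's pivot tolerance handling is sensitive to rescaled rows.
solve_lp_backend <- function(model, n_iter = NULL) {
  F <- length(model$w_rep)
  cc <- rep(1, 2 * F)
  # d-space coefficients for a w-space row a: [a*w_rep, -a*w_rep], rhs - a.w_rep
  Aw <- model$C * rep(model$w_rep, each = nrow(model$C))
  rhs <- model$constraints$limit - as.vector(model$C %*% model$w_rep)

  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL; A3 <- NULL; b3 <- NULL
  push <- function(row, r, dir) {
    if (dir == "eq") {
      if (r < 0) { row <- -row; r <- -r }
      A3 <<- rbind(A3, row); b3 <<- c(b3, r)
    } else {
      if (dir == "ge") { row <- -row; r <- -r }   # normalise to <=
      if (r < 0) {                                # backend wants b >= 0
        A2 <<- rbind(A2, -row); b2 <<- c(b2, -r)
      } else {
        A1 <<- rbind(A1, row); b1 <<- c(b1, r)
      }
    }
  }
  if (nrow(Aw) > 0) {
    for (i in seq_len(nrow(Aw))) {
      push(c(Aw[i, ], -Aw[i, ]), rhs[i], model$constraints$direction[i])
    }
  }
  # bounds: d- <= 1 for all foods; d+ <= max_increase_rd for non-exempt
  for (i in seq_len(F)) {
    row <- numeric(2 * F); row[F + i] <- 1
    push(row, 1, "le")
  }
  for (i in which(!model$exempt)) {
    row <- numeric(2 * F); row[i] <- 1
    push(row, model$max_increase_rd, "le")
  }

  n_iter <- n_iter %||% (200 + 20 * (2 * F + length(b1) + length(b2) + length(b3)))
  res <- tryCatch(
    boot::simplex(a = cc, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = FALSE, n.iter = n_iter),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    return(list(status = "solver_error", message = conditionMessage(res)))
  }
  status <- switch(as.character(res$solved),
                   "1" = "optimal", "-1" = "infeasible", "solver_error")
  list(status = status, x = if (status == "optimal") unname(as.vector(res$soln)),
       objective = if (status == "optimal") unname(res$value),
       message = if (status == "solver_error") "iteration limit reached")
}

#' Solve a diet optimisation model
#'
#' Runs the simplex backend on a model from [build_model()]. At an optimum
#' the objective value must agree with the total relative deviation
#' recomputed from the optimised weights (to 1e-6 relative), which verifies
#' that no deviation split carries simultaneous positive \eqn{d^+} and
#' \eqn{d^-} slack.
#'
#' @param model A `diet_lp_model`.
#' @param diagnostics Complete the solution with [diet_diagnostics()].
#' @return An object of class `diet_solution` with `status` one of
#'   `"optimal"`, `"infeasible"`, `"solver_error"`; when optimal it carries
#'   the per-food weights, TRD, ARD (%), active constraints, CO2eq, cost and
#'   the food-change census.
#' @export
solve_model <- function(model, diagnostics = TRUE) {
  stopifnot(inherits(model, "diet_lp_model"))
  res <- solve_lp_backend(model)
  F <- length(model$w_rep)
  sol <- structure(
    list(status = res$status, model = model, message = res$message,
         weights = NULL, trd = NA_real_, ard_percent = NA_real_,
         objective = NA_real_),
    class = "diet_solution"
  )
  if (res$status != "optimal") return(sol)

  dp <- res$x[seq_len(F)]; dm <- res$x[F + seq_len(F)]
  w_opt <- model$w_rep * (1 + dp - dm)
  w_opt[abs(w_opt) < 1e-12] <- 0
  rd <- relative_deviation(w_opt, model$w_rep)
  trd <- sum(abs(rd))
  if (abs(trd - res$objective) > 1e-6 * max(1, abs(res$objective))) {
    abort(sprintf(paste0("Solver objective (%.8g) disagrees with recomputed ",
                         "sum of |RD| (%.8g)"), res$objective, trd),
          class = "dietshift_solver_error")
  }
  sol$weights <- tibble(
    food_id = model$food_ids, group = model$foods$group,
    exempt = model$exempt, w_rep = model$w_rep, w_opt = w_opt, rd = rd
  )
  sol$objective <- res$objective
  sol$trd <- trd
  sol$ard_percent <- 100 * trd / F
  if (diagnostics) sol <- diet_diagnostics(sol)
  sol
}

#' Complete a solution with diagnostics
#'
#' Adds the active-constraint list (rows meeting their limit to within
#' `tol_active` relative), the food-change census (removed below `tol_zero`
#' grams; reduced / increased by more than `tol_change` relative deviation
#' among the remaining foods), the average relative deviation, and the diet's
#' CO2eq and cost as dot products over the optimised weights.
#'
#' @param solution An optimal `diet_solution`.
#' @param tol_active Relative tolerance for "meets exactly 100 % of its
#'   limit".
#' @param tol_zero Weight (g/day) below which a food counts as removed.
#' @param tol_change Minimum |RD| for a food to count as changed.
#' @return The completed `diet_solution`.
#' @export
diet_diagnostics <- function(solution, tol_active = 1e-6, tol_zero = 0.01,
                             tol_change = 1e-3) {
  stopifnot(inherits(solution, "diet_solution"))
  if (solution$status != "optimal") {
    abort("diagnostics need an optimal solution",
          class = "dietshift_validation_error")
  }
  model <- solution$model
  w_opt <- solution$weights$w_opt
  achieved <- as.vector(model$C %*% w_opt)
  audit <- model$constraints |>
    mutate(achieved = achieved,
           ratio = if_else(.data$limit != 0, achieved / .data$limit, NA_real_),
           active = if_else(.data$limit != 0,
                            abs(achieved / .data$limit - 1) <= tol_active,
                            abs(achieved) <= tol_active))
  rd <- solution$weights$rd
  removed <- solution$weights$food_id[w_opt < tol_zero]
  left <- !(solution$weights$food_id %in% removed)
  solution$constraint_audit <- audit
  solution$active_constraints <- filter(audit, .data$active)
  solution$removed <- removed
  solution$reduced <- solution$weights$food_id[left & rd < -tol_change]
  solution$increased <- solution$weights$food_id[left & rd > tol_change]
  solution$co2eq_g <- sum(model$foods$co2eq_g_per_g * w_opt)
  solution$cost_sek <- sum(model$foods$price_sek_per_g * w_opt)
  solution$energy_kcal <- sum(model$foods$energy_kcal_per_g * w_opt)
  solution$baseline_energy_kcal <- model$energy_kcal
  solution$baseline_co2eq_g <- sum(model$foods$co2eq_g_per_g * model$w_rep)
  solution$baseline_cost_sek <- sum(model$foods$price_sek_per_g * model$w_rep)
  solution
}

#' @export
print.diet_solution <- function(x, ...) {
  cat("<diet_solution> status:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  TRD %.4g | ARD %.1f %% | foods %d (removed %d, reduced %d, increased %d)\n",
                x$trd, x$ard_percent, nrow(x$weights),
                length(x$removed %||% character(0)),
                length(x$reduced %||% character(0)),
                length(x$increased %||% character(0))))
    if (!is.null(x$co2eq_g)) {
      cat(sprintf("  CO2eq %.0f g/day | cost %.1f SEK/day\n",
                  x$co2eq_g, x$cost_sek))
    }
  }
  invisible(x)
}

#' Optimise the total population and every cluster under a model grid
#'
#' Forms one baseline diet per target (the total population, labelled
#' `"TotPop"`, plus each cluster in `labels`) and solves every model
#' specification in `specs` for each, covering the standard two-family,
#' four-target model grid.
#'
#' @param population A [survey_population()].
#' @param labels Tibble with `person_id`, `cluster`; `NULL` optimises the
#'   total population only.
#' @param specs Named list of [diet_model_spec()]s, e.g.
#'   [default_spec_grid()].
#' @return Tibble with one row per (target, model): columns `target`,
#'   `model`, `status`, `trd`, `ard_percent`, `co2eq_g`, `cost_sek`,
#'   `n_foods` and a `solution` list-column.
#' @export
optimise_all <- function(population, labels = NULL,
                         specs = default_spec_grid()) {
  stopifnot(inherits(population, "survey_population"))
  targets <- list(TotPop = NULL)
  if (!is.null(labels)) {
    for (cl in sort(unique(labels$cluster))) {
      ids <- labels$person_id[labels$cluster == cl]
      if (length(ids) == 0) {
        inform(paste0("Cluster ", cl, " is empty; skipped"))
        next
      }
      targets[[paste0("cluster_", cl)]] <- ids
    }
  }
  rows <- list()
  for (tg in names(targets)) {
    base <- baseline_diet(population, targets[[tg]])
    for (sp in names(specs)) {
      model <- build_model(base, population$foods, specs[[sp]])
      sol <- solve_model(model)
      rows[[length(rows) + 1L]] <- tibble(
        target = tg, model = sp, status = sol$status,
        trd = sol$trd, ard_percent = sol$ard_percent,
        co2eq_g = sol$co2eq_g %||% NA_real_,
        cost_sek = sol$cost_sek %||% NA_real_,
        n_foods = base$n_foods, solution = list(sol)
      )
    }
  }
  bind_rows(rows)
}
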