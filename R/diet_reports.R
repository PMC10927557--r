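#' Percentage change in greenhouse-gas emissions
#'
#' `100 * (optimised - baseline) / baseline`, rounded half away from zero to
#' an integer for report display (the raw value is what the `digits`
#' argument controls; `digits = NULL` returns it unrounded).
#'
#' @param baseline_g,optimised_g Daily dietary CO2eq (g/day); baseline must
#'   be positive.
#' @param digits Integer digits for half-away-from-zero rounding, or `NULL`.
#' @return Percentage change.
#' @export
ghge_change_percent <- function(baseline_g, optimised_g, digits = 0) {
  if (any(baseline_g <= 0)) {
    abort("baseline_g must be positive", class = "dietshift_validation_error")
  }
  pct <- 100 * (optimised_g - baseline_g) / baseline_g
  if (is.null(digits)) pct else round_half_away(pct, digits)
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Food-group deviations of an optimised diet
#'
#' Per-food-group baseline and optimised weights (sums over member foods)
#' and the group-level relative deviation in percent. Groups absent from the
#' baseline are omitted.
#'
#' @param solution An optimal `diet_solution`.
#' @return Tibble: `group`, `baseline_g`, `optimised_g`, `rd_percent`.
#' @export
group_deviation <- function(solution) {
  stopifnot(inherits(solution, "diet_solution"),
            solution$status == "optimal")
  solution$weights |>
    group_by(.data$group) |>
    summarise(baseline_g = sum(.data$w_rep),
              optimised_g = sum(.data$w_opt), .groups = "drop") |>
    mutate(rd_percent = 100 * (.data$optimised_g - .data$baseline_g) /
             .data$baseline_g)
}

#' Cluster-vs-total-population dietary shift differences
#'
#' For every food group, the optimisation-induced change in energy-adjusted
#' intake (optimised minus baseline, g/MJ/day, using each target's own
#' baseline energy) in a cluster, minus the corresponding change for the
#' total population. Zero everywhere means the cluster needs exactly the
#' shifts the population-average model prescribes.
#'
#' @param cluster_solutions Named list of optimal `diet_solution`s, one per
#'   cluster.
#' @param totpop_solution Optimal `diet_solution` of the total population.
#' @return Tibble: `group`, `target`, `shift_cluster`, `shift_totpop`,
#'   `difference` (all g/MJ/day).
#' @export
shift_difference <- function(cluster_solutions, totpop_solution) {
  shift_of <- function(sol) {
    mj <- kcal_to_mj(sol$model$energy_kcal)
    sol$weights |>
      group_by(.data$group) |>
      summarise(shift = (sum(.data$w_opt) - sum(.data$w_rep)) / mj,
                .groups = "drop")
  }
  tot <- shift_of(totpop_solution) |> rename(shift_totpop = "shift")
  purrr::imap_dfr(cluster_solutions, function(sol, nm) {
    shift_of(sol) |>
      rename(shift_cluster = "shift") |>
      mutate(target = nm)
  }) |>
    inner_join(tot, by = "group") |>
    mutate(difference = .data$shift_cluster - .data$shift_totpop) |>
    select("group", "target", "shift_cluster", "shift_totpop", "difference")
}

#' Energy shares by EAT-Lancet category
#'
#' Splits each food's energy over the EAT-Lancet categories with its `el_*`
#' energy fractions and expresses each category as a percent of total
#' dietary energy (shares sum to 100).
#'
#' @param weights Tibble with `food_id` and a weight column (`w_opt`, or
#'   `w_rep` via `use`), e.g. `solution$weights`; or an optimal
#'   `diet_solution`.
#' @param foods Composition tibble carrying the `el_*` columns.
#' @param use Which weight column to use, `"w_opt"` (default) or `"w_rep"`.
#' @return Tibble: `category`, `energy_kcal`, `share_percent`.
#' @export
eatlancet_shares <- function(weights, foods, use = "w_opt") {
  if (inherits(weights, "diet_solution")) weights <- weights$weights
  el_cols <- grep("^el_", names(foods), value = TRUE)
  if (length(el_cols) == 0) {
    abort("Composition table has no el_* category columns",
          class = "dietshift_schema_error")
  }
  fd <- weights |> inner_join(foods, by = "food_id", suffix = c("", ".y"))
  frac_sum <- rowSums(fd[el_cols])
  if (any(abs(frac_sum - 1) > 1e-6)) {
    abort("EAT-Lancet energy fractions must sum to 1 for every food",
          class = "dietshift_validation_error")
  }
  w <- fd[[use]]
  energy <- w * fd$energy_kcal_per_g
  cat_energy <- purrr::map_dbl(el_cols, function(cl) sum(energy * fd[[cl]]))
  tibble(
    category = sub("^el_", "", el_cols),
    energy_kcal = cat_energy,
    share_percent = 100 * cat_energy / sum(cat_energy)
  )
}

#' Summary diagnostics table for a grid of solutions
#'
#' One row per optimised diet: CO2eq, its percentage change versus baseline
#' (integer, half away from zero), cost, ARD (one decimal) and the
#' foods-available/removed/reduced/increased census — the standard summary
#' table of this modelling workflow. Raw values stay available from the
#' solutions themselves.
#'
#' @param results Output of [optimise_all()].
#' @return Tibble of per-diet diagnostics.
#' @export
results_table <- function(results) {
  purrr::pmap_dfr(results, function(target, model, status, solution, ...) {
    if (status != "optimal") {
      return(tibble(target = target, model = model, status = status,
                    co2eq_g = NA_real_, co2eq_change_percent = NA_real_,
                    cost_sek = NA_real_, ard_percent = NA_real_,
                    foods_available = NA_integer_, foods_removed = NA_integer_,
                    foods_reduced = NA_integer_, foods_increased = NA_integer_))
    }
    tibble(
      target = target, model = model, status = status,
      co2eq_g = solution$co2eq_g,
      co2eq_change_percent =
        ghge_change_percent(solution$baseline_co2eq_g, solution$co2eq_g),
      cost_sek = solution$cost_sek,
      ard_percent = round_half_away(solution$ard_percent, 1),
      foods_available = nrow(solution$weights),
      foods_removed = length(solution$removed),
      foods_reduced = length(solution$reduced),
      foods_increased = length(solution$increased)
    )
  })
}

#' Bar chart of food-group relative deviations
#'
#' @param deviations Output of [group_deviation()], optionally with an extra
#'   `target` column to facet by.
#' @return A ggplot object.
#' @export
plot_group_deviation <- function(deviations) {
  p <- ggplot2::ggplot(deviations,
                       ggplot2::aes(x = .data$rd_percent,
                                    y = stats::reorder(.data$group, .data$rd_percent))) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Deviation from baseline intake (%)", y = NULL)
  if ("target" %in% names(deviations)) {
    p <- p + ggplot2::facet_wrap(~target)
  }
  p
}

#' Dot chart of cluster-vs-total-population shift differences
#'
#' @param shifts Output of [shift_difference()].
#' @return A ggplot object.
#' @export
plot_shift_difference <- function(shifts) {
  ggplot2::ggplot(shifts,
                  ggplot2::aes(x = .data$difference, y = .data$group,
                               colour = .data$target)) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Shift difference vs total-population model (g/MJ/day)",
                  y = NULL, colour = "Cluster")
}

#' Column chart of EAT-Lancet energy shares
#'
#' @param shares Output of [eatlancet_shares()], optionally with an extra
#'   `diet` column to dodge by.
#' @return A ggplot object.
#' @export
plot_energy_shares <- function(shares) {
  aes <- if ("diet" %in% names(shares)) {
    ggplot2::aes(x = .data$category, y = .data$share_percent,
                 fill = .data$diet)
  } else {
    ggplot2::aes(x = .data$category, y = .data$share_percent)
  }
  ggplot2::ggplot(shares, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Share of dietary energy (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
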