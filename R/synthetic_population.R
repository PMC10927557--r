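#' Food-group catalogue for the synthetic survey generator
#'
#' Design-time constants for the 24 food groups the generator emulates: a
#' baseline gram share of the daily diet, energy density (kcal/g), CO2eq
#' intensity (g/g), retail price (SEK/g), nutrient densities (iron mg/g,
#' vitamin D ug/g, sodium mg/g, added sugars / saturated fat / fibre /
#' carbohydrate / protein / fat g/g), guideline category fractions
#' (whole-grain, fruit-and-vegetable, seafood, red/processed-meat) and the
#' EAT-Lancet energy-category split (`el_*` columns, summing to 1 per group).
#' Values are order-of-magnitude realistic for cooked, as-eaten foods in a
#' Northern-European diet; they are synthetic stand-ins, not survey data.
#'
#' @return A tibble with one row per food group.
#' @export
food_group_catalogue <- function() {
  tb <- tibble::tribble(
    ~group,                            ~base_share_g, ~energy_kcal_per_g, ~co2eq_g_per_g, ~price_sek_per_g,
    "Red meat",                        70,  2.00, 17.0, 0.100,
    "Processed meat",                  50,  2.60, 10.0, 0.090,
    "Poultry",                         45,  1.70,  3.0, 0.080,
    "Seafood",                         35,  1.50,  4.0, 0.130,
    "Offal",                            3,  1.40,  8.0, 0.060,
    "Dairy",                          320,  0.90,  1.40, 0.012,
    "Eggs",                            25,  1.40,  2.0, 0.050,
    "Pasta and rice dishes with meat/fish", 80, 1.50, 4.0, 0.050,
    "Pasta and rice dishes with dairy/eggs", 40, 1.40, 2.0, 0.045,
    "Vegetable oils",                  12,  8.80,  1.50, 0.020,
    "Vegetables",                     160,  0.35,  0.80, 0.035,
    "Potatoes",                       120,  0.80,  0.30, 0.015,
    "Pulses",                          20,  1.00,  0.70, 0.020,
    "Fruits and berries",             160,  0.55,  0.60, 0.030,
    "Nuts and seeds",                  12,  6.00,  1.50, 0.110,
    "Meat alternatives",                8,  1.50,  2.50, 0.090,
    "Dairy alternatives",              30,  0.50,  0.40, 0.015,
    "Mixed/animal fats",               20,  7.20,  7.00, 0.060,
    "Cereals/grains",                 200,  2.50,  0.80, 0.030,
    "Rice",                            40,  1.30,  2.50, 0.020,
    "Savoury snacks",                  18,  4.80,  2.50, 0.080,
    "Sugar and sweets",                50,  4.30,  2.50, 0.090,
    "Drinks other than milk",         800,  0.32,  0.40, 0.010,
    "Other",                           90,  1.50,  2.00, 0.040
  )
  nut <- tibble::tribble(
    ~group, ~iron, ~vitamin_d, ~sodium, ~added_sugars, ~saturated_fat, ~fibre, ~carbohydrate, ~protein, ~fat,
    "Red meat",                        0.022, 0.002, 0.60, 0,     0.035, 0,     0.010, 0.260, 0.090,
    "Processed meat",                  0.015, 0.001, 9.00, 0.010, 0.080, 0,     0.030, 0.150, 0.210,
    "Poultry",                         0.007, 0.002, 0.70, 0,     0.015, 0,     0.010, 0.270, 0.060,
    "Seafood",                         0.005, 0.080, 0.80, 0,     0.008, 0,     0.005, 0.200, 0.050,
    "Offal",                           0.080, 0.010, 0.80, 0,     0.020, 0,     0.020, 0.200, 0.050,
    "Dairy",                           0.001, 0.008, 0.80, 0.010, 0.035, 0,     0.050, 0.050, 0.055,
    "Eggs",                            0.018, 0.018, 1.30, 0,     0.030, 0,     0.010, 0.120, 0.100,
    "Pasta and rice dishes with meat/fish", 0.010, 0.001, 3.00, 0.005, 0.020, 0.010, 0.180, 0.080, 0.050,
    "Pasta and rice dishes with dairy/eggs", 0.008, 0.002, 3.00, 0.005, 0.025, 0.010, 0.200, 0.060, 0.040,
    "Vegetable oils",                  0,     0,     0,    0,     0.070, 0,     0,     0,     0.990,
    "Vegetables",                      0.008, 0,     0.20, 0,     0.001, 0.025, 0.050, 0.020, 0.003,
    "Potatoes",                        0.004, 0,     0.10, 0,     0.001, 0.020, 0.170, 0.020, 0.001,
    "Pulses",                          0.025, 0,     0.30, 0,     0.001, 0.070, 0.140, 0.080, 0.010,
    "Fruits and berries",              0.003, 0,     0.01, 0,     0.001, 0.020, 0.120, 0.007, 0.003,
    "Nuts and seeds",                  0.030, 0,     0.10, 0,     0.060, 0.080, 0.200, 0.200, 0.500,
    "Meat alternatives",               0.030, 0.008, 4.00, 0,     0.010, 0.050, 0.080, 0.180, 0.080,
    "Dairy alternatives",              0.005, 0.011, 0.40, 0.030, 0.003, 0.005, 0.070, 0.010, 0.015,
    "Mixed/animal fats",               0,     0.005, 5.00, 0,     0.450, 0,     0.005, 0.005, 0.800,
    "Cereals/grains",                  0.012, 0,     4.00, 0.010, 0.004, 0.060, 0.450, 0.090, 0.030,
    "Rice",                            0.002, 0,     0.10, 0,     0.001, 0.010, 0.280, 0.027, 0.003,
    "Savoury snacks",                  0.010, 0,     8.00, 0.020, 0.020, 0.030, 0.500, 0.060, 0.250,
    "Sugar and sweets",                0.005, 0,     0.50, 0.550, 0.120, 0.010, 0.600, 0.050, 0.180,
    "Drinks other than milk",          0.001, 0,     0.10, 0.055, 0,     0.001, 0.070, 0.002, 0.001,
    "Other",                           0.005, 0,     6.00, 0.050, 0.020, 0.010, 0.120, 0.030, 0.090
  )
  frac <- tibble::tribble(
    ~group, ~whole_grain_frac, ~fv_frac, ~seafood_frac, ~rpm_frac, ~consume_prob,
    "Red meat",                        0,    0,    0, 1,    0.97,
    "Processed meat",                  0,    0,    0, 1,    0.95,
    "Poultry",                         0,    0,    0, 0,    0.90,
    "Seafood",                         0,    0,    1, 0,    0.90,
    "Offal",                           0,    0,    0, 0,    0.15,
    "Dairy",                           0,    0,    0, 0,    1.00,
    "Eggs",                            0,    0,    0, 0,    0.92,
    "Pasta and rice dishes with meat/fish", 0.05, 0.05, 0.05, 0.25, 0.65,
    "Pasta and rice dishes with dairy/eggs", 0.05, 0.05, 0, 0,   0.50,
    "Vegetable oils",                  0,    0,    0, 0,    0.55,
    "Vegetables",                      0,    1,    0, 0,    1.00,
    "Potatoes",                        0,    0,    0, 0,    0.95,
    "Pulses",                          0,    0.50, 0, 0,    0.55,
    "Fruits and berries",              0,    1,    0, 0,    1.00,
    "Nuts and seeds",                  0,    0,    0, 0,    0.60,
    "Meat alternatives",               0,    0,    0, 0,    0.25,
    "Dairy alternatives",              0,    0,    0, 0,    0.40,
    "Mixed/animal fats",               0,    0,    0, 0,    0.93,
    "Cereals/grains",                  0.35, 0,    0, 0,    1.00,
    "Rice",                            0.08, 0,    0, 0,    0.85,
    "Savoury snacks",                  0,    0,    0, 0,    0.60,
    "Sugar and sweets",                0,    0,    0, 0,    0.95,
    "Drinks other than milk",          0,    0.10, 0, 0,    1.00,
    "Other",                           0,    0.10, 0, 0,    0.98
  )
  el <- tibble::tribble(
    ~group, ~el_whole_grains, ~el_tubers, ~el_vegetables, ~el_fruits, ~el_dairy, ~el_beef_lamb_pork, ~el_poultry, ~el_eggs, ~el_fish, ~el_legumes, ~el_nuts, ~el_added_fats, ~el_added_sugars,
    "Red meat",                        0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0,
    "Processed meat",                  0, 0, 0, 0, 0, 0.85, 0.15, 0, 0, 0, 0, 0, 0,
    "Poultry",                         0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0,
    "Seafood",                         0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0,
    "Offal",                           0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0,
    "Dairy",                           0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0,
    "Eggs",                            0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0,
    "Pasta and rice dishes with meat/fish", 0.45, 0, 0.05, 0, 0, 0.30, 0, 0, 0, 0, 0, 0.20, 0,
    "Pasta and rice dishes with dairy/eggs", 0.50, 0, 0.05, 0, 0.30, 0, 0, 0, 0, 0, 0, 0.15, 0,
    "Vegetable oils",                  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0,
    "Vegetables",                      0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    "Potatoes",                        0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    "Pulses",                          0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0,
    "Fruits and berries",              0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    "Nuts and seeds",                  0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0,
    "Meat alternatives",               0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0,
    "Dairy alternatives",              0.5, 0, 0, 0, 0.5, 0, 0, 0, 0, 0, 0, 0, 0,
    "Mixed/animal fats",               0, 0, 0, 0, 0.5, 0, 0, 0, 0, 0, 0, 0.5, 0,
    "Cereals/grains",                  1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    "Rice",                            1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    "Savoury snacks",                  0, 0.5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.5, 0,
    "Sugar and sweets",                0, 0, 0, 0, 0.1, 0, 0, 0, 0, 0, 0, 0.3, 0.6,
    "Drinks other than milk",          0, 0, 0, 0.4, 0, 0, 0, 0, 0, 0, 0, 0, 0.6,
    "Other",                           0, 0, 0.2, 0, 0, 0, 0, 0, 0, 0, 0, 0.5, 0.3
  )
  tb |>
    left_join(nut, by = "group") |>
    left_join(frac, by = "group") |>
    left_join(el, by = "group") |>
    mutate(exempt = .data$group %in% EXEMPT_GROUPS)
}

#' Archetype specification for the synthetic generator
#'
#' An archetype is one planted eating pattern: a vector of target diet-weight
#' shares over the 24 food groups, a lognormal noise level and a head count.
#'
#' @param name Archetype label (conventionally `"classic"`, `"nutrich"`,
#'   `"lowclim"`).
#' @param group_weights Named nonnegative numeric over the catalogue groups;
#'   rescaled to sum to 1.
#' @param noise_cv Coefficient of variation of the per-food multiplicative
#'   lognormal noise.
#' @param n_individuals Number of individuals drawn from this archetype.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, group_weights, noise_cv = 0.2,
                           n_individuals = 50) {
  if (any(group_weights < 0)) {
    abort("group_weights must be nonnegative",
          class = "dietshift_validation_error")
  }
  if (noise_cv < 0) {
    abort("noise_cv must be nonnegative", class = "dietshift_validation_error")
  }
  s <- sum(group_weights)
  if (s <= 0) abort("group_weights must have positive sum")
  structure(
    list(name = name, group_weights = group_weights / s,
         noise_cv = noise_cv, n_individuals = n_individuals),
    class = "archetype_spec"
  )
}

#' The three default eating-pattern archetypes
#'
#' Emulates the three patterns a Swedish-style adult survey separates into:
#' `classic` (meat- and potato-heavy, low fruit/vegetables, highest-emission),
#' `nutrich` (nutrient-dense animal foods, nuts and vegetables) and `lowclim`
#' (plant-forward, pulse-rich, sweet-toothed, lowest-emission). Head counts
#' follow the roughly balanced 39/30/31 % split of the three observed
#' clusters, scaled to `n_total`.
#'
#' @param n_total Total number of individuals across the three archetypes.
#' @param noise_cv Per-food lognormal noise level shared by all archetypes.
#' @return List of three [archetype_spec()]s.
#' @export
default_archetypes <- function(n_total = 150, noise_cv = 0.2) {
  cat24 <- food_group_catalogue()
  base <- setNames(cat24$base_share_g, cat24$group)
  mult <- function(...) {
    m <- setNames(rep(1, length(base)), names(base))
    adj <- c(...)
    m[names(adj)] <- adj
    base * m
  }
  classic <- mult("Red meat" = 1.6, "Processed meat" = 1.6, "Potatoes" = 1.5,
                  "Vegetables" = 0.6, "Fruits and berries" = 0.6,
                  "Pulses" = 0.5, "Nuts and seeds" = 0.5, "Seafood" = 0.8,
                  "Dairy" = 1.1, "Sugar and sweets" = 1.1, "Rice" = 0.8)
  nutrich <- mult("Red meat" = 1.1, "Poultry" = 1.3, "Seafood" = 1.5,
                  "Eggs" = 1.4, "Dairy" = 1.2, "Nuts and seeds" = 2.5,
                  "Vegetables" = 1.4, "Fruits and berries" = 1.2,
                  "Mixed/animal fats" = 1.2, "Sugar and sweets" = 0.7,
                  "Drinks other than milk" = 0.9)
  lowclim <- mult("Red meat" = 0.45, "Processed meat" = 0.5, "Poultry" = 0.8,
                  "Dairy" = 0.8, "Vegetables" = 1.5, "Pulses" = 2.5,
                  "Fruits and berries" = 1.3, "Sugar and sweets" = 1.4,
                  "Cereals/grains" = 1.1, "Dairy alternatives" = 2,
                  "Meat alternatives" = 2.5, "Seafood" = 0.9)
  n <- round(n_total * c(0.3934, 0.2972, 0.3094))
  n[1] <- n_total - sum(n[-1])
  list(
    archetype_spec("classic", classic, noise_cv, n[1]),
    archetype_spec("nutrich", nutrich, noise_cv, n[2]),
    archetype_spec("lowclim", lowclim, noise_cv, n[3])
  )
}

#' Generator configuration
#'
#' @param seed Integer seed; a fixed seed makes [generate_population()]
#'   byte-reproducible.
#' @param n_foods_per_group Food items drawn per food group.
#' @param archetypes List of [archetype_spec()]s (at least 2 for clustering
#'   work).
#' @param energy_target_kcal Named vector `c(mean = , sd = )` for the daily
#'   energy draw; sex offsets (x0.88 female, x1.15 male) are applied to the
#'   mean.
#' @param sex_ratio Overall probability of drawing a female individual;
#'   archetypes get small offsets so sex composition differs across clusters.
#' @param drv_table [nutrient_constraints()] the generated population must be
#'   feasible against (checked by a feasibility probe at generation time).
#' @param food_keep_range Range of the per-individual probability of keeping
#'   each food within a consumed group (zero-intake sparsity).
#' @param sparsity Logical; when `FALSE`, every individual consumes every
#'   food of every group (no group skipping, no within-group subsetting),
#'   which makes archetype diets deterministic up to noise.
#' @param probe_cap_g CO2eq cap used in the generation-time feasibility probe.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_foods_per_group = 2L,
                             archetypes = default_archetypes(),
                             energy_target_kcal = c(mean = 2100, sd = 280),
                             sex_ratio = 0.56,
                             drv_table = default_drv_table(),
                             food_keep_range = c(0.6, 0.8),
                             sparsity = TRUE,
                             probe_cap_g = 1570) {
  stopifnot(length(archetypes) >= 1, n_foods_per_group >= 1)
  structure(
    list(seed = as.integer(seed), n_foods_per_group = as.integer(n_foods_per_group),
         archetypes = archetypes, energy_target_kcal = energy_target_kcal,
         sex_ratio = sex_ratio, drv_table = drv_table,
         food_keep_range = food_keep_range, sparsity = isTRUE(sparsity),
         probe_cap_g = probe_cap_g),
    class = "generator_config"
  )
}

# Build the synthetic composition table: n_foods_per_group items per group
# with mild lognormal jitter around the catalogue densities.
synth_foods <- function(catalogue, n_per_group) {
  rows <- catalogue[rep(seq_len(nrow(catalogue)), each = n_per_group), ]
  rows$item <- rep(seq_len(n_per_group), times = nrow(catalogue))
  jit <- function(x, sdlog = 0.10) x * rlnorm(length(x), -sdlog^2 / 2, sdlog)
  nut_cols <- c("energy_kcal_per_g", "co2eq_g_per_g", "price_sek_per_g",
                "iron", "vitamin_d", "sodium", "added_sugars",
                "saturated_fat", "fibre", "carbohydrate", "protein", "fat")
  for (cl in nut_cols) rows[[cl]] <- jit(rows[[cl]])
  rows |>
    mutate(
      food_id = sprintf("f%02d_%d", match(.data$group, catalogue$group), .data$item),
      name = paste0(.data$group, " item ", .data$item)
    ) |>
    select("food_id", "name", "group", "energy_kcal_per_g", "co2eq_g_per_g",
           "price_sek_per_g", "whole_grain_frac", "fv_frac", "seafood_frac",
           "rpm_frac", "exempt", dplyr::all_of(c("iron", "vitamin_d", "sodium",
           "added_sugars", "saturated_fat", "fibre", "carbohydrate", "protein",
           "fat")), dplyr::starts_with("el_"), "consume_prob")
}

#' Generate a synthetic survey population with planted cluster structure
#'
#' Draws individuals from the configured archetypes. Each individual consumes
#' a random subset of the foods in each consumed group (so rarely-eaten
#' groups exist for the prevalence filter to act on); intakes are the
#' archetype's group-weight shares split across kept foods, perturbed by
#' multiplicative lognormal noise with the archetype's coefficient of
#' variation, then rescaled so the individual's diet meets their drawn energy
#' target exactly. A feasibility probe (nutrient + guideline constraints and
#' the CO2eq cap on the population-mean diet, foods allowed to triple, exempt
#' groups unbounded) runs at generation time; an infeasible draw is an error
#' naming the violated constraint.
#'
#' @param config A [generator_config()].
#' @param probe Logical; run the generation-time feasibility probe.
#' @return List with `population` (a [survey_population()]) and `true_labels`
#'   (tibble `person_id`, `true_cluster`).
#' @export
generate_population <- function(config, probe = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  out <- withr::with_seed(config$seed, generate_population_impl(config))
  if (probe) {
    spec <- diet_model_spec(co2eq_cap_g = config$probe_cap_g,
                            drv_table = config$drv_table)
    pr <- feasibility_probe(out$population, spec)
    if (!pr$feasible) {
      abort(paste0("Generated population is LP-infeasible; first violated ",
                   "constraint: ", pr$witness),
            class = "dietshift_generation_error")
    }
  }
  out
}

generate_population_impl <- function(config) {
  catalogue <- food_group_catalogue()
  foods <- synth_foods(catalogue, config$n_foods_per_group)
  consume_prob <- setNames(foods$consume_prob, foods$food_id)
  group_of <- setNames(foods$group, foods$food_id)
  e_dens <- setNames(foods$energy_kcal_per_g, foods$food_id)
  foods <- select(foods, -"consume_prob")

  em <- config$energy_target_kcal[["mean"]]
  es <- config$energy_target_kcal[["sd"]]
  sex_off <- c(classic = -0.11, nutrich = 0.02, lowclim = 0.10)
  age_off <- c(classic = 3, nutrich = 1, lowclim = -4)
  inc_off <- c(classic = 0, nutrich = 0.20, lowclim = 0.05)

  indiv_rows <- list(); intake_rows <- list(); labels <- list()
  pid <- 0L
  for (a in config$archetypes) {
    gw <- a$group_weights
    p_fem <- min(max(config$sex_ratio + (sex_off[a$name] %||% 0), 0.05), 0.95)
    sdlog <- sqrt(log(1 + a$noise_cv^2))
    for (i in seq_len(a$n_individuals)) {
      pid <- pid + 1L
      person <- sprintf("p%04d", pid)
      sex <- if (runif(1) < p_fem) "female" else "male"
      mu <- em * if (sex == "female") 0.88 else 1.15
      energy <- min(max(rnorm(1, mu, es), mu - 3 * es, 1200),
                    mu + 3 * es, 3500)
      age <- round(min(max(rnorm(1, 48 + (age_off[a$name] %||% 0), 15), 18), 80))
      income <- rlnorm(1, log(310000) + (inc_off[a$name] %||% 0), 0.35)

      # which groups and foods this individual eats
      grp_names <- names(gw)[gw > 0]
      w <- numeric(0)
      keep_p <- runif(1, config$food_keep_range[1], config$food_keep_range[2])
      for (g in grp_names) {
        fids <- names(group_of)[group_of == g]
        if (config$sparsity && runif(1) > consume_prob[fids[1]]) next
        kept <- if (config$sparsity) fids[runif(length(fids)) < keep_p] else fids
        if (length(kept) == 0) kept <- sample(fids, 1)
        share <- gw[[g]] / length(kept)
        noise <- if (a$noise_cv > 0) {
          rlnorm(length(kept), -sdlog^2 / 2, sdlog)
        } else rep(1, length(kept))
        w <- c(w, setNames(share * noise, kept))
      }
      # rescale grams so total energy equals the drawn target
      w <- w * energy / sum(w * e_dens[names(w)])
      indiv_rows[[pid]] <- tibble(person_id = person, sex = sex, age = age,
                                  income = income)
      intake_rows[[pid]] <- tibble(person_id = person, food_id = names(w),
                                   intake_g_day = unname(w))
      labels[[pid]] <- tibble(person_id = person, true_cluster = a$name)
    }
  }
  nutrients <- tibble(
    nutrient_id = c("iron", "vitamin_d", "sodium", "added_sugars",
                    "saturated_fat", "fibre", "carbohydrate", "protein", "fat"),
    unit = c("mg", "ug", "mg", "g", "g", "g", "g", "g", "g")
  )
  pop <- survey_population(foods, bind_rows(indiv_rows),
                           bind_rows(intake_rows), nutrients)
  list(population = pop, true_labels = bind_rows(labels))
}

#' Probe LP feasibility of a population's mean diet
#'
#' Builds the optimisation model for the population-mean baseline diet under
#' `spec` and solves it. When infeasible, constraints are re-added one family
#' at a time (energy, then each nutrient row, then each guideline row, then
#' the CO2eq cap) and the first constraint whose addition makes the programme
#' infeasible is reported as the witness.
#'
#' @param population A [survey_population()].
#' @param spec A [diet_model_spec()].
#' @return List with `feasible` (logical) and, when infeasible, `witness`
#'   (a constraint id).
#' @export
feasibility_probe <- function(population, spec) {
  base <- baseline_diet(population)
  model <- build_model(base, population$foods, spec)
  sol <- solve_model(model, diagnostics = FALSE)
  if (sol$status == "optimal") return(list(feasible = TRUE, witness = NULL))
  ids <- model$constraints$id
  for (j in seq_along(ids)) {
    sub <- subset_model(model, ids[seq_len(j)])
    s <- solve_model(sub, diagnostics = FALSE)
    if (s$status != "optimal") {
      return(list(feasible = FALSE, witness = ids[j]))
    }
  }
  list(feasible = FALSE, witness = "unknown (joint infeasibility)")
}
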