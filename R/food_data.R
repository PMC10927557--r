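#' Survey populations: foods, individuals and intakes
#'
#' A `survey_population` bundles the three tables every other stage of the
#' pipeline consumes: a food-composition table (one row per food item, with
#' energy and nutrient densities per gram, CO2eq intensity, price, food-group
#' label and guideline category fractions), an individual table (sex, age,
#' income) and a long intake table of mean daily intakes in g/day.
#'
#' @param foods Tibble of food items; see [read_population()] for columns.
#' @param individuals Tibble with `person_id`, `sex` (`"female"`/`"male"`),
#'   `age` (years), `income` (SEK/year).
#' @param intakes Long tibble with `person_id`, `food_id`, `intake_g_day`.
#' @param nutrients Tibble with `nutrient_id`, `unit` describing the nutrient
#'   columns of `foods` (amount of `unit` per g of food).
#'
#' @return An object of class `survey_population`.
#' @export
survey_population <- function(foods, individuals, intakes, nutrients) {
  foods <- as_tibble(foods)
  individuals <- as_tibble(individuals)
  intakes <- as_tibble(intakes)
  nutrients <- as_tibble(nutrients)

  check_columns(foods, c("food_id", "name", "group", "energy_kcal_per_g",
                         "co2eq_g_per_g", "price_sek_per_g", "whole_grain_frac",
                         "fv_frac", "seafood_frac", "rpm_frac", "exempt"),
                "composition")
  check_columns(individuals, c("person_id", "sex", "age", "income"),
                "individuals")
  check_columns(intakes, c("person_id", "food_id", "intake_g_day"),
                "consumption")
  check_columns(nutrients, c("nutrient_id", "unit"), "nutrient catalogue")

  missing_nut <- setdiff(nutrients$nutrient_id, names(foods))
  if (length(missing_nut) > 0) {
    abort(paste0("Composition table lacks nutrient column(s): ",
                 paste(missing_nut, collapse = ", ")), class = "dietshift_schema_error")
  }
  unknown <- setdiff(intakes$food_id, foods$food_id)
  if (length(unknown) > 0) {
    abort(paste0("Consumption refers to food_id(s) absent from composition: ",
                 paste(unique(unknown), collapse = ", ")),
          class = "dietshift_validation_error")
  }
  bad <- which(intakes$intake_g_day < 0)
  if (length(bad) > 0) {
    abort(paste0("Negative intake in consumption row(s): ",
                 paste(head(bad, 5L), collapse = ", ")),
          class = "dietshift_validation_error")
  }
  num_cols <- c("energy_kcal_per_g", "co2eq_g_per_g", "price_sek_per_g",
                nutrients$nutrient_id)
  for (cl in num_cols) {
    if (any(foods[[cl]] < 0)) {
      abort(paste0("Negative values in composition column '", cl, "'"),
            class = "dietshift_validation_error")
    }
  }
  for (cl in c("whole_grain_frac", "fv_frac", "seafood_frac", "rpm_frac")) {
    if (any(foods[[cl]] < 0 | foods[[cl]] > 1)) {
      abort(paste0("Column '", cl, "' must lie in [0, 1]"),
            class = "dietshift_validation_error")
    }
  }
  el_cols <- grep("^el_", names(foods), value = TRUE)
  if (length(el_cols) > 0) {
    el_sum <- rowSums(foods[el_cols])
    if (any(abs(el_sum - 1) > 1e-9)) {
      abort("EAT-Lancet energy fractions (el_*) must sum to 1 for every food",
            class = "dietshift_validation_error")
    }
  }

  structure(
    list(foods = foods, individuals = individuals, intakes = intakes,
         nutrients = nutrients),
    class = "survey_population"
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", what, " table: ",
                 paste(missing, collapse = ", ")),
          class = "dietshift_schema_error")
  }
  invisible(df)
}

#' @export
print.survey_population <- function(x, ...) {
  cat("<survey_population>\n")
  cat("  individuals:", nrow(x$individuals), "\n")
  cat("  foods:      ", nrow(x$foods), "in",
      length(unique(x$foods$group)), "groups\n")
  cat("  nutrients:  ", paste(x$nutrients$nutrient_id, collapse = ", "), "\n")
  invisible(x)
}

#' Read a survey population from CSV tables
#'
#' Reads the two standard input tables. `composition_csv` has one row per food
#' with columns `food_id,name,group,energy_kcal_per_g,co2eq_g_per_g,
#' price_sek_per_g,whole_grain_frac,fv_frac,seafood_frac,rpm_frac,exempt`, one
#' column per nutrient and one `el_`-prefixed column per EAT-Lancet energy
#' category. `consumption_csv` is long format:
#' `person_id,sex,age,income,food_id,intake_g_day`.
#'
#' @param composition_csv,consumption_csv Paths to the two CSV files.
#' @param nutrients Optional nutrient catalogue tibble (`nutrient_id`, `unit`).
#'   By default every composition column that is not a fixed schema column and
#'   not `el_`-prefixed is taken as a nutrient with unit `"per_g"`.
#' @return A [survey_population()].
#' @export
read_population <- function(composition_csv, consumption_csv, nutrients = NULL) {
  foods <- readr::read_csv(composition_csv, show_col_types = FALSE)
  cons <- readr::read_csv(consumption_csv, show_col_types = FALSE)
  check_columns(cons, c("person_id", "sex", "age", "income", "food_id",
                        "intake_g_day"), "consumption")
  fixed <- c("food_id", "name", "group", "energy_kcal_per_g", "co2eq_g_per_g",
             "price_sek_per_g", "whole_grain_frac", "fv_frac", "seafood_frac",
             "rpm_frac", "exempt")
  if (is.null(nutrients)) {
    nut_cols <- setdiff(names(foods), c(fixed, grep("^el_", names(foods), value = TRUE)))
    nutrients <- tibble(nutrient_id = nut_cols, unit = "per_g")
  }
  individuals <- cons |>
    distinct(.data$person_id, .data$sex, .data$age, .data$income)
  intakes <- cons |> select("person_id", "food_id", "intake_g_day")
  survey_population(foods, individuals, intakes, nutrients)
}

#' Write a survey population to CSV tables
#'
#' Inverse of [read_population()]: writes `composition.csv` and
#' `consumption.csv` into `dir`.
#'
#' @param population A [survey_population()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "survey_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp_path <- file.path(dir, "composition.csv")
  cons_path <- file.path(dir, "consumption.csv")
  readr::write_csv(population$foods, comp_path)
  cons <- population$intakes |>
    left_join(population$individuals, by = "person_id") |>
    select("person_id", "sex", "age", "income", "food_id", "intake_g_day")
  readr::write_csv(cons, cons_path)
  invisible(c(composition = comp_path, consumption = cons_path))
}

#' Daily energy intake per individual
#'
#' Energy intake is the intake-weighted sum of energy densities,
#' \eqn{\sum_f w_f e_f} in kcal/day, also returned in MJ/day
#' (1 kcal = 4.184 kJ). Individuals with zero total energy cannot be
#' energy-standardised (g/MJ) and raise an error.
#'
#' @param population A [survey_population()].
#' @return Tibble with `person_id`, `energy_kcal`, `energy_mj`.
#' @export
energy_intake <- function(population) {
  stopifnot(inherits(population, "survey_population"))
  if (nrow(population$intakes) == 0) {
    abort("No intakes recorded; energy intake undefined",
          class = "dietshift_validation_error")
  }
  e <- population$intakes |>
    left_join(select(population$foods, "food_id", "energy_kcal_per_g"),
              by = "food_id") |>
    group_by(.data$person_id) |>
    summarise(energy_kcal = sum(.data$intake_g_day * .data$energy_kcal_per_g),
              .groups = "drop")
  # individuals with no intake rows at all have no energy either
  missing <- setdiff(population$individuals$person_id, e$person_id)
  if (length(missing) > 0 || any(e$energy_kcal <= 0)) {
    zero <- c(missing, e$person_id[e$energy_kcal <= 0])
    abort(paste0("Zero total energy intake for individual(s): ",
                 paste(head(zero, 5L), collapse = ", ")),
          class = "dietshift_validation_error")
  }
  e |> mutate(energy_mj = kcal_to_mj(.data$energy_kcal))
}

#' Population- or cluster-mean baseline diet
#'
#' Averages the per-individual intakes (zeros included for non-consumers) of a
#' set of individuals into one baseline diet; only foods with positive mean
#' intake are retained as decision variables downstream.
#'
#' @param population A [survey_population()].
#' @param ids Optional character/typeof-person_id vector selecting a subset of
#'   individuals (e.g. one cluster). Default: all individuals.
#' @return An object of class `baseline_diet`: a list with `weights` (tibble
#'   `food_id`, `w_rep` in g/day), `energy_kcal`, `n_foods`, `sex_counts`.
#' @export
baseline_diet <- function(population, ids = NULL) {
  stopifnot(inherits(population, "survey_population"))
  indiv <- population$individuals
  if (!is.null(ids)) {
    indiv <- filter(indiv, .data$person_id %in% ids)
    if (nrow(indiv) == 0) abort("No individuals selected for baseline diet")
  }
  n <- nrow(indiv)
  w <- population$intakes |>
    filter(.data$person_id %in% indiv$person_id) |>
    group_by(.data$food_id) |>
    summarise(w_rep = sum(.data$intake_g_day) / n, .groups = "drop") |>
    filter(.data$w_rep > 0)
  w <- w |>
    left_join(select(population$foods, "food_id", "energy_kcal_per_g"),
              by = "food_id")
  structure(
    list(
      weights = select(w, "food_id", "w_rep"),
      energy_kcal = sum(w$w_rep * w$energy_kcal_per_g),
      n_foods = nrow(w),
      sex_counts = c(n_female = sum(indiv$sex == "female"),
                     n_male = sum(indiv$sex == "male"))
    ),
    class = "baseline_diet"
  )
}

#' @export
print.baseline_diet <- function(x, ...) {
  cat("<baseline_diet> ", x$n_foods, " foods, ",
      round(x$energy_kcal), " kcal/day (",
      x$sex_counts[["n_female"]], "F/", x$sex_counts[["n_male"]], "M)\n",
      sep = "")
  invisible(x)
}
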