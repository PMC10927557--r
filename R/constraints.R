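#' Nutrient constraint tables (dietary reference values)
#'
#' A nutrient constraint table has one row per bound with columns
#' `nutrient_id`, `kind` (`"lower"` or `"upper"`; a recommended range is two
#' rows), `basis` (`"absolute"`: amount/day in the nutrient's own unit, or
#' `"percent_energy"`: percent of dietary energy, converted with Atwater
#' factors 4/4/9 kcal per g for carbohydrate/protein/fat and 7 for alcohol)
#' and sex-specific limits `limit_female`, `limit_male`. Where limits differ
#' by sex, the model weights them by the sex composition of the target group.
#'
#' @param df Data frame with the columns above.
#' @return A validated tibble of class `nutrient_constraints`.
#' @export
nutrient_constraints <- function(df) {
  df <- as_tibble(df)
  check_columns(df, c("nutrient_id", "kind", "basis", "limit_female",
                      "limit_male"), "constraints")
  if (!all(df$kind %in% c("lower", "upper"))) {
    abort("kind must be 'lower' or 'upper' (express a range as two rows)",
          class = "dietshift_validation_error")
  }
  if (!all(df$basis %in% c("absolute", "percent_energy"))) {
    abort("basis must be 'absolute' or 'percent_energy'",
          class = "dietshift_validation_error")
  }
  if (any(df$limit_female < 0) || any(df$limit_male < 0)) {
    abort("Nutrient limits must be nonnegative",
          class = "dietshift_validation_error")
  }
  both <- df |>
    tidyr::pivot_wider(id_cols = "nutrient_id", names_from = "kind",
                       values_from = "limit_female", values_fn = min)
  if (all(c("lower", "upper") %in% names(both))) {
    rng <- both |> filter(!is.na(.data$lower) & !is.na(.data$upper))
    if (any(rng$lower >= rng$upper)) {
      abort("Range constraints need lower < upper",
            class = "dietshift_validation_error")
    }
  }
  class(df) <- c("nutrient_constraints", class(df))
  df
}

#' Read nutrient constraints from CSV
#'
#' @param path CSV with columns `nutrient_id,kind,basis,limit_female,limit_male`.
#' @return A [nutrient_constraints()] tibble.
#' @export
read_nutrient_constraints <- function(path) {
  nutrient_constraints(readr::read_csv(path, show_col_types = FALSE))
}

#' Default dietary reference values
#'
#' A stand-in DRV table in the spirit of the Nordic Nutrition Recommendations
#' 2012: lower bounds for iron, vitamin D and fibre; upper bounds for sodium,
#' added sugars and saturated fat; recommended ranges (two rows each) for
#' carbohydrate, protein and fat as percent of energy. The authoritative
#' values for any given survey live in its own documentation; these defaults
#' exist so the pipeline runs end to end and are deliberately conventional.
#'
#' Units: iron mg/day, vitamin D ug/day, fibre g/day, sodium mg/day;
#' percent_energy rows are in E%.
#'
#' @return A [nutrient_constraints()] tibble.
#' @export
default_drv_table <- function() {
  nutrient_constraints(tibble::tribble(
    ~nutrient_id,    ~kind,   ~basis,           ~limit_female, ~limit_male,
    "iron",          "lower", "absolute",        15,            9,
    "vitamin_d",     "lower", "absolute",        10,           10,
    "fibre",         "lower", "absolute",        25,           35,
    "sodium",        "upper", "absolute",        2400,         2400,
    "added_sugars",  "upper", "percent_energy",  10,           10,
    "saturated_fat", "upper", "percent_energy",  10,           10,
    "carbohydrate",  "lower", "percent_energy",  45,           45,
    "carbohydrate",  "upper", "percent_energy",  60,           60,
    "protein",       "lower", "percent_energy",  10,           10,
    "protein",       "upper", "percent_energy",  20,           20,
    "fat",           "lower", "percent_energy",  25,           25,
    "fat",           "upper", "percent_energy",  40,           40
  ))
}

#' Food-based dietary guideline constraints
#'
#' The four Swedish food-based dietary guidelines used as obligatory model
#' constraints: at least 500 g/day fruit and vegetables, at least 45 g/day
#' seafood, at least 75 g whole grains per 10 MJ of dietary energy, and at
#' most 71 g/day red and processed meat. Category membership of a food is
#' fractional (`fv_frac`, `seafood_frac`, `rpm_frac`, `whole_grain_frac` in
#' the composition table), so composite dishes count partially.
#'
#' @param fruit_veg_g,seafood_g,whole_grains_g_per_10mj,red_processed_meat_g
#'   Guideline limits; defaults are the published values.
#' @return Tibble with `category`, `direction`, `limit`, `basis`.
#' @export
fbdg_constraints <- function(fruit_veg_g = 500, seafood_g = 45,
                             whole_grains_g_per_10mj = 75,
                             red_processed_meat_g = 71) {
  lims <- c(fruit_veg_g, seafood_g, whole_grains_g_per_10mj,
            red_processed_meat_g)
  if (any(lims <= 0)) {
    abort("FBDG limits must be positive", class = "dietshift_validation_error")
  }
  tibble(
    category = c("fruit_veg", "seafood", "whole_grains", "red_processed_meat"),
    direction = c("ge", "ge", "ge", "le"),
    limit = lims,
    basis = c("absolute", "absolute", "per_10MJ", "absolute")
  )
}

#' Specify one diet optimisation model
#'
#' One cell of the model grid: which constraint families apply, the per-food
#' acceptability bound, and an optional greenhouse-gas cap. The two published
#' model families are `diet_model_spec()` (nutrient + guideline constrained)
#' and `diet_model_spec(co2eq_cap_g = 1570)` (additionally capped at 1.57 kg
#' CO2eq/day, the climate-boundary level).
#'
#' @param use_fbdg,use_drv Logical; apply guideline / nutrient constraints.
#' @param co2eq_cap_g Optional cap on total daily CO2eq in grams (`NULL` for
#'   none).
#' @param max_increase_rd Maximum relative deviation upwards for non-exempt
#'   foods; the default 2 encodes the +200 % rule. Foods in the exempt groups
#'   (Pulses, Nuts and seeds, Dairy alternatives, Meat alternatives, Vegetable
#'   oils) may increase without bound.
#' @param drv_table A [nutrient_constraints()] table.
#' @param fbdg_table An [fbdg_constraints()] table.
#' @return An object of class `diet_model_spec`.
#' @export
diet_model_spec <- function(use_fbdg = TRUE, use_drv = TRUE,
                            co2eq_cap_g = NULL, max_increase_rd = 2,
                            drv_table = default_drv_table(),
                            fbdg_table = fbdg_constraints()) {
  if (!is.null(co2eq_cap_g) && co2eq_cap_g < 0) {
    abort("co2eq_cap_g must be positive or NULL",
          class = "dietshift_validation_error")
  }
  if (max_increase_rd < 0) {
    abort("max_increase_rd must be nonnegative",
          class = "dietshift_validation_error")
  }
  structure(
    list(use_fbdg = use_fbdg, use_drv = use_drv, co2eq_cap_g = co2eq_cap_g,
         max_increase_rd = max_increase_rd, drv_table = drv_table,
         fbdg_table = fbdg_table),
    class = "diet_model_spec"
  )
}

#' The standard two-model grid
#'
#' @param cap_g CO2eq cap for the climate-constrained family (g/day).
#' @return Named list of two [diet_model_spec()]s: `"base"` (no cap) and
#'   `"cap"` (greenhouse-gas capped).
#' @export
default_spec_grid <- function(cap_g = 1570) {
  list(base = diet_model_spec(),
       cap = diet_model_spec(co2eq_cap_g = cap_g))
}
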