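# Small in-code fixtures shared across test files.

# Composition tibble with sensible defaults; every argument recycles.
toy_foods <- function(food_id, group = "Vegetables", energy = 1, co2 = 0,
                      price = 0, iron = 0, wg = 0, fv = 0, sf = 0, rpm = 0,
                      el_vegetables = 1) {
  n <- length(food_id)
  tibble::tibble(
    food_id = food_id,
    name = food_id,
    group = rep_len(group, n),
    energy_kcal_per_g = rep_len(energy, n),
    co2eq_g_per_g = rep_len(co2, n),
    price_sek_per_g = rep_len(price, n),
    whole_grain_frac = rep_len(wg, n),
    fv_frac = rep_len(fv, n),
    seafood_frac = rep_len(sf, n),
    rpm_frac = rep_len(rpm, n),
    exempt = rep_len(group, n) %in%
      c("Pulses", "Nuts and seeds", "Dairy alternatives",
        "Meat alternatives", "Vegetable oils"),
    iron = rep_len(iron, n),
    el_vegetables = rep_len(el_vegetables, n)
  )
}

# Population from a person-by-food intake matrix (zeros dropped).
toy_population <- function(foods, intakes, sex = NULL) {
  intakes <- as.matrix(intakes)
  np <- nrow(intakes)
  pid <- sprintf("p%02d", seq_len(np))
  sex <- sex %||% rep_len(c("female", "male"), np)
  long <- do.call(rbind, lapply(seq_len(np), function(i) {
    keep <- intakes[i, ] > 0
    data.frame(person_id = pid[i], food_id = foods$food_id[keep],
               intake_g_day = intakes[i, keep])
  }))
  survey_population(
    foods = foods,
    individuals = tibble::tibble(person_id = pid, sex = sex,
                                 age = 40, income = 3e5),
    intakes = tibble::as_tibble(long),
    nutrients = tibble::tibble(nutrient_id = "iron", unit = "mg")
  )
}

# A model spec with no nutrient/guideline constraints (energy + bounds only).
bare_spec <- function(co2eq_cap_g = NULL, max_increase_rd = 2) {
  diet_model_spec(use_fbdg = FALSE, use_drv = FALSE,
                  co2eq_cap_g = co2eq_cap_g,
                  max_increase_rd = max_increase_rd)
}

# The default synthetic population is expensive enough to share per session.
.gen_cache <- new.env(parent = emptyenv())
default_gen <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.gen_cache[[key]])) {
    .gen_cache[[key]] <- generate_population(generator_config(seed = seed))
  }
  .gen_cache[[key]]
}

# Cached clustering + optimisation grid on the default population.
default_results <- function(seed = 1) {
  key <- paste0("res", seed)
  if (is.null(.gen_cache[[key]])) {
    gen <- default_gen(seed)
    feats <- build_features(gen$population)
    cl <- ward_cluster(canberra_dist(feats), 3, features = feats)
    .gen_cache[[key]] <- list(
      gen = gen, features = feats, clusters = cl,
      results = optimise_all(gen$population, tidy(cl))
    )
  }
  .gen_cache[[key]]
}
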