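# A baseline over given foods/weights via a one-person population.
baseline_of <- function(foods, w_rep, sex = "female") {
  pop <- toy_population(foods, matrix(w_rep, nrow = 1), sex = sex)
  baseline_diet(pop)
}

test_that("relative deviation is (w_opt - w_rep) / w_rep", {
  expect_equal(relative_deviation(100, 100), 0)
  expect_equal(relative_deviation(0, 57), -1)
  expect_equal(relative_deviation(300, 100), 2)  # the +200 % bound
  expect_equal(relative_deviation(c(50, 150), c(100, 100)), c(-0.5, 0.5))
  expect_error(relative_deviation(1, 0), class = "dietshift_validation_error")
})

test_that("a feasible baseline is returned unchanged with zero deviation", {
  foods <- toy_foods("a", energy = 2)
  base <- baseline_of(foods, 100)
  sol <- solve_model(build_model(base, foods, bare_spec()))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$trd, 0)
  expect_equal(tidy(sol)$w_opt, 100)
  expect_equal(length(sol$removed), 0)
  expect_equal(length(sol$reduced), 0)
  expect_equal(length(sol$increased), 0)
})

test_that("a two-food instance matches the analytic solution", {
  # isocaloric foods (1 kcal/g), baseline (100, 100), energy fixed at 200.
  # Requiring >= 150 g of food b forces w = (50, 150):
  # RD = (-1/2, +1/2), TRD = 1.
  foods <- toy_foods(c("a", "b"), energy = 1, iron = c(0, 1))
  base <- baseline_of(foods, c(100, 100))
  drv <- nutrient_constraints(tibble::tibble(
    nutrient_id = "iron", kind = "lower", basis = "absolute",
    limit_female = 150, limit_male = 150))
  spec <- diet_model_spec(use_fbdg = FALSE, drv_table = drv)
  sol <- solve_model(build_model(base, foods, spec))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$trd, 1, tolerance = 1e-9)
  w <- tidy(sol)
  expect_equal(w$w_opt[w$food_id == "a"], 50, tolerance = 1e-9)
  expect_equal(w$w_opt[w$food_id == "b"], 150, tolerance = 1e-9)
  expect_true("drv_iron_lower" %in% sol$active_constraints$id)
})

test_that("objective matches the grid oracle on random small instances", {
  withr::local_seed(99)
  for (rep in 1:8) {
    F <- sample(2:3, 1)
    foods <- toy_foods(sprintf("f%d", 1:F),
                       energy = runif(F, 0.5, 3),
                       co2 = runif(F, 0.2, 5),
                       iron = runif(F, 0, 0.05))
    w_rep <- runif(F, 50, 200)
    base <- baseline_of(foods, w_rep)
    # constraints anchored at a random feasible interior point
    wstar <- w_rep * runif(F, 0.3, 2.5)
    e <- foods$energy_kcal_per_g
    wstar <- wstar * base$energy_kcal / sum(wstar * e)
    if (any(wstar > 3 * w_rep)) next
    iron_star <- sum(wstar * foods$iron)
    co2_star <- sum(wstar * foods$co2eq_g_per_g)
    drv <- nutrient_constraints(tibble::tibble(
      nutrient_id = "iron", kind = "lower", basis = "absolute",
      limit_female = iron_star * 0.95, limit_male = iron_star * 0.95))
    spec <- diet_model_spec(use_fbdg = FALSE, drv_table = drv,
                            co2eq_cap_g = co2_star * 1.1)
    model <- build_model(base, foods, spec)
    sol <- solve_model(model)
    expect_equal(sol$status, "optimal")
    oracle <- grid_oracle(model)
    expect_lt(abs(sol$trd - oracle), if (F == 2) 2e-3 else 6e-3)
    # grid optimum can never beat the LP optimum
    expect_gte(oracle, sol$trd - 1e-9)
  }
})

test_that("bounds confine non-exempt foods and free exempt ones", {
  foods <- toy_foods(c("meat", "pulse"),
                     group = c("Red meat", "Pulses"),
                     energy = 1, iron = c(0.005, 0.05))
  base <- baseline_of(foods, c(200, 10))
  # 210 kcal fixes total weight at 210 g; iron >= 3.75 mg then has the
  # unique solution (150, 60): pulses rise 6-fold, beyond any +200 % bound
  drv <- nutrient_constraints(tibble::tibble(
    nutrient_id = "iron", kind = "lower", basis = "absolute",
    limit_female = 3.75, limit_male = 3.75))
  spec <- diet_model_spec(use_fbdg = FALSE, drv_table = drv)
  sol <- solve_model(build_model(base, foods, spec))
  expect_equal(sol$status, "optimal")
  w <- tidy(sol)
  expect_equal(w$w_opt[w$food_id == "meat"], 150, tolerance = 1e-8)
  expect_equal(w$w_opt[w$food_id == "pulse"], 60, tolerance = 1e-8)
  expect_gt(relative_deviation(w$w_opt[w$food_id == "pulse"], 10), 2)
})

test_that("an unsatisfiable emission cap is reported infeasible", {
  foods <- toy_foods("a", energy = 1, co2 = 1)
  base <- baseline_of(foods, 100)
  sol <- solve_model(build_model(base, foods, bare_spec(co2eq_cap_g = 1)),
                     diagnostics = FALSE)
  expect_equal(sol$status, "infeasible")
  expect_null(sol$weights)
})

test_that("every optimal solution passes an independent feasibility audit", {
  res <- default_results()
  for (i in seq_len(nrow(res$results))) {
    sol <- res$results$solution[[i]]
    expect_equal(sol$status, "optimal")
    model <- sol$model
    achieved <- as.vector(model$C %*% tidy(sol)$w_opt)
    for (r in seq_len(nrow(model$constraints))) {
      lim <- model$constraints$limit[r]
      tol <- 1e-6 * max(1, abs(lim))
      switch(model$constraints$direction[r],
        eq = expect_lt(abs(achieved[r] - lim), tol),
        ge = expect_gte(achieved[r], lim - tol),
        le = expect_lte(achieved[r], lim + tol))
    }
    # deviation-split linearisation left no simultaneous slack
    expect_equal(sol$objective, sum(abs(tidy(sol)$rd)), tolerance = 1e-6)
    # energy conservation
    expect_equal(sol$energy_kcal, sol$baseline_energy_kcal,
                 tolerance = 1e-6)
  }
})

test_that("optimal deviation is monotone in the emission cap", {
  res <- default_results()
  pop <- res$gen$population
  base <- baseline_diet(pop)
  caps <- c(1400, 1570, 1900, 2500, 3600)
  trds <- sapply(caps, function(cap) {
    sol <- solve_model(build_model(base, pop$foods,
                                   diet_model_spec(co2eq_cap_g = cap)),
                       diagnostics = FALSE)
    expect_equal(sol$status, "optimal")
    sol$trd
  })
  expect_true(all(diff(trds) <= 1e-7))
  # the capped family can never deviate less than the uncapped one
  for (tg in unique(res$results$target)) {
    sub <- res$results[res$results$target == tg, ]
    expect_gte(sub$trd[sub$model == "cap"], sub$trd[sub$model == "base"] - 1e-9)
  }
})

test_that("scaling weights and absolute limits rescales the diet, not the TRD", {
  withr::local_seed(5)
  foods <- toy_foods(c("a", "b", "c"), energy = c(1, 2, 0.5),
                     co2 = c(3, 1, 0.5), iron = c(0.02, 0, 0.01))
  w_rep <- c(120, 80, 240)
  drv0 <- tibble::tibble(nutrient_id = "iron", kind = "lower",
                         basis = "absolute", limit_female = 5,
                         limit_male = 5)
  solve_scaled <- function(cc) {
    base <- baseline_of(foods, w_rep * cc)
    drv <- nutrient_constraints(dplyr::mutate(
      drv0, limit_female = .data$limit_female * cc,
      limit_male = .data$limit_male * cc))
    spec <- diet_model_spec(use_fbdg = FALSE, drv_table = drv,
                            co2eq_cap_g = 500 * cc)
    solve_model(build_model(base, foods, spec))
  }
  s1 <- solve_scaled(1)
  s3 <- solve_scaled(3)
  expect_equal(s1$status, "optimal")
  expect_equal(s3$trd, s1$trd, tolerance = 1e-8)
  expect_equal(tidy(s3)$w_opt, 3 * tidy(s1)$w_opt, tolerance = 1e-6)
})

test_that("diagnostics census matches manual inspection of a 4-food toy", {
  # d is emission-heavy and nutritionally idle: the cap drives it to zero
  foods <- toy_foods(c("a", "b", "c", "d"), energy = 1,
                     co2 = c(0.1, 0.1, 0.1, 10))
  base <- baseline_of(foods, c(100, 100, 100, 50))
  # total weight is fixed at 350 g; at cap 35 even the first gram of d
  # breaches it, so d must vanish and 50 g backfill across a, b, c
  sol <- solve_model(build_model(base, foods, bare_spec(co2eq_cap_g = 35)))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$removed, "d")
  expect_gte(length(sol$increased), 1)
  expect_equal(sum(tidy(sol)$w_opt), 350, tolerance = 1e-8)
  expect_equal(sol$co2eq_g, 35, tolerance = 1e-6)
  expect_true("co2eq_cap" %in% sol$active_constraints$id)
  expect_equal(sol$ard_percent, 100 * sol$trd / 4)

  # solution at baseline: empty census, no binding inequality
  sol0 <- solve_model(build_model(base, foods, bare_spec()))
  expect_equal(length(sol0$removed) + length(sol0$reduced) +
                 length(sol0$increased), 0)
})

test_that("optimise_all covers targets and a lone cluster mirrors TotPop", {
  gen <- default_gen()
  labels <- tibble::tibble(person_id = gen$population$individuals$person_id,
                           cluster = 1L)
  res <- optimise_all(gen$population, labels)
  expect_equal(sort(unique(res$target)), c("TotPop", "cluster_1"))
  for (m in c("base", "cap")) {
    sub <- res[res$model == m, ]
    expect_equal(sub$trd[sub$target == "TotPop"],
                 sub$trd[sub$target == "cluster_1"], tolerance = 1e-9)
  }
  # capped solutions respect the cap
  expect_true(all(res$co2eq_g[res$model == "cap"] <= 1570 + 1e-6))
})

test_that("model building validates its inputs", {
  foods <- toy_foods("a")
  base <- baseline_of(foods, 100)
  drv <- nutrient_constraints(tibble::tibble(
    nutrient_id = "zinc", kind = "lower", basis = "absolute",
    limit_female = 1, limit_male = 1))
  expect_error(
    build_model(base, foods, diet_model_spec(use_fbdg = FALSE,
                                             drv_table = drv)),
    "zinc", class = "dietshift_schema_error")
  expect_error(diet_model_spec(max_increase_rd = -1),
               class = "dietshift_validation_error")
})
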