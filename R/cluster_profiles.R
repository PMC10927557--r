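#' SHEIA15-style healthy-eating score
#'
#' Sums nine intake-to-recommendation ratios after clipping each to [0, 1],
#' giving a score in [0, 9], and assigns the conventional levels: low (< 4
#' points), medium (4-7 points), high (> 7 points).
#'
#' @param component_ratios Numeric vector of exactly nine finite ratios
#'   (baseline intake over recommended intake per dietary component).
#' @return An object of class `sheia15_result`: list with
#'   `component_ratios`, `clipped_ratios`, `score`, `level`.
#' @export
sheia15 <- function(component_ratios) {
  if (length(component_ratios) != 9 || !all(is.finite(component_ratios))) {
    abort("sheia15 requires exactly nine finite component ratios",
          class = "dietshift_validation_error")
  }
  clipped <- pmin(pmax(component_ratios, 0), 1)
  score <- sum(clipped)
  level <- if (score < 4) "low" else if (score <= 7) "medium" else "high"
  structure(
    list(component_ratios = component_ratios, clipped_ratios = clipped,
         score = score, level = level),
    class = "sheia15_result"
  )
}

#' @export
print.sheia15_result <- function(x, ...) {
  cat(sprintf("<sheia15_result> score %.2f / 9 (%s)\n", x$score, x$level))
  invisible(x)
}

#' Stand-in component definitions for the healthy-eating score
#'
#' The authoritative nine components and their reference amounts are survey
#' configuration; these defaults are clearly-labelled stand-ins assembled
#' from the named Swedish dietary-guideline quantities so the scorer runs end
#' to end: four adequacy components (ratio = intake / recommendation) and
#' five moderation components (ratio = limit / intake, so staying within the
#' limit clips to full credit).
#'
#' @return Tibble with `component`, `type` (`"adequacy"`/`"moderation"`),
#'   `quantity` (how the intake aggregate is computed) and `reference`.
#' @export
sheia15_components <- function() {
  tibble::tribble(
    ~component,           ~type,        ~quantity,              ~reference,
    "fruit_veg",          "adequacy",   "fv_g_day",             500,
    "seafood",            "adequacy",   "seafood_g_day",        45,
    "whole_grains",       "adequacy",   "wholegrain_g_10mj",    75,
    "fibre",              "adequacy",   "fibre_g_day",          28,
    "pulses_nuts",        "adequacy",   "pulses_nuts_g_day",    25,
    "red_processed_meat", "moderation", "rpm_g_day",            71,
    "added_sugars",       "moderation", "added_sugars_epct",    10,
    "saturated_fat",      "moderation", "saturated_fat_epct",   10,
    "sodium",             "moderation", "sodium_mg_day",        2400
  )
}

# Mean-diet aggregates needed by the score components, for one set of
# individuals.
sheia15_aggregates <- function(population, ids = NULL) {
  base <- baseline_diet(population, ids)
  fd <- base$weights |> inner_join(population$foods, by = "food_id")
  w <- fd$w_rep
  e_kcal <- sum(w * fd$energy_kcal_per_g)
  e_mj <- kcal_to_mj(e_kcal)
  c(
    fv_g_day = sum(w * fd$fv_frac),
    seafood_g_day = sum(w * fd$seafood_frac),
    wholegrain_g_10mj = sum(w * fd$whole_grain_frac) / (e_mj / 10),
    fibre_g_day = sum(w * fd$fibre),
    pulses_nuts_g_day = sum(w[fd$group %in% c("Pulses", "Nuts and seeds")]),
    rpm_g_day = sum(w * fd$rpm_frac),
    added_sugars_epct = 100 * sum(w * fd$added_sugars) * 4 / e_kcal,
    saturated_fat_epct = 100 * sum(w * fd$saturated_fat) * 9 / e_kcal,
    sodium_mg_day = sum(w * fd$sodium)
  )
}

#' Score the mean diet of each cluster (or the whole population)
#'
#' Computes the nine component ratios from a mean baseline diet (adequacy:
#' intake / reference; moderation: reference / intake, full credit when
#' intake is zero) and passes them to [sheia15()].
#'
#' @param population A [survey_population()].
#' @param labels Optional tibble `person_id`, `cluster`; `NULL` scores the
#'   total population.
#' @param components Component configuration, see [sheia15_components()].
#' @return Tibble with `target`, `score`, `level` and a `result` list-column.
#' @export
sheia15_score <- function(population, labels = NULL,
                          components = sheia15_components()) {
  targets <- list(TotPop = NULL)
  if (!is.null(labels)) {
    for (cl in sort(unique(labels$cluster))) {
      targets[[paste0("cluster_", cl)]] <-
        labels$person_id[labels$cluster == cl]
    }
  }
  purrr::map_dfr(names(targets), function(tg) {
    agg <- sheia15_aggregates(population, targets[[tg]])
    ratios <- purrr::map2_dbl(components$quantity, seq_len(nrow(components)),
      function(q, i) {
        val <- agg[[q]]
        ref <- components$reference[i]
        if (components$type[i] == "adequacy") val / ref
        else if (val <= 0) 1 else ref / val
      })
    res <- sheia15(ratios)
    tibble(target = tg, score = res$score, level = res$level,
           result = list(res))
  })
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Rank-based k-sample test (midranks, tie-corrected) followed by Dunn's
#' pairwise z-tests on mean ranks with Benjamini-Hochberg adjustment of the
#' two-sided p-values.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return List with `statistic`, `df`, `p_value` (the Kruskal-Wallis test)
#'   and `posthoc`, a tibble of pairwise comparisons (`group1`, `group2`,
#'   `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- factor(groups)
  kw <- kruskal.test(values, groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  ph <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    num <- mean(r[groups == g1]) - mean(r[groups == g2])
    den <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
    z <- num / den
    tibble(group1 = g1, group2 = g2, z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  ph$p_adjusted <- p.adjust(ph$p_value, method = "BH")
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, posthoc = ph)
}

#' Compare clusters on diet, emission and demographic variables
#'
#' Post-hoc characterisation of a partition: Kruskal-Wallis with Dunn/BH
#' post-hoc for the energy-adjusted food-group intakes (g/MJ), dietary CO2eq
#' (g/MJ) and income (right-skewed variables); one-way ANOVA with Tukey's
#' HSD for age; Pearson's chi-squared (no continuity correction) for the
#' cluster-by-sex table. Variables constant across all individuals are
#' skipped with a notice. Significance is flagged at alpha = 0.05.
#'
#' @param population A [survey_population()].
#' @param labels Tibble `person_id`, `cluster` (at least 2 clusters with at
#'   least 2 members each).
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `dietshift_comparison`: tibble with `variable`,
#'   `test`, `statistic`, `df`, `p_value`, `significant`, `note` and a
#'   `posthoc` list-column.
#' @export
compare_clusters <- function(population, labels, alpha = 0.05) {
  stopifnot(inherits(population, "survey_population"))
  check_columns(labels, c("person_id", "cluster"), "labels")
  sizes <- table(labels$cluster)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need at least two clusters with at least two members each",
          class = "dietshift_validation_error")
  }
  gm <- group_intake_per_mj(population) |>
    inner_join(labels, by = "person_id") |>
    inner_join(population$individuals, by = "person_id")
  grp <- factor(gm$cluster)

  kw_vars <- c(setdiff(names(gm), c("person_id", "cluster", "sex", "age",
                                    "income")), "income")
  rows <- purrr::map_dfr(kw_vars, function(v) {
    x <- gm[[v]]
    if (sd(x) == 0) {
      inform(paste0("Variable '", v, "' is constant; test skipped"))
      return(tibble(variable = v, test = "skipped", statistic = NA_real_,
                    df = NA_real_, p_value = NA_real_, significant = NA,
                    note = "constant variable", posthoc = list(NULL)))
    }
    kd <- kruskal_dunn(x, grp)
    tibble(variable = v, test = "kruskal_wallis", statistic = kd$statistic,
           df = kd$df, p_value = kd$p_value,
           significant = kd$p_value <= alpha, note = NA_character_,
           posthoc = list(kd$posthoc))
  })

  age_row <- if (sd(gm$age) == 0) {
    inform("Variable 'age' is constant; test skipped")
    tibble(variable = "age", test = "skipped", statistic = NA_real_,
           df = NA_real_, p_value = NA_real_, significant = NA,
           note = "constant variable", posthoc = list(NULL))
  } else {
    fit <- aov(age ~ cluster, data = transform(gm, cluster = grp))
    an <- summary(fit)[[1]]
    tk <- as.data.frame(TukeyHSD(fit)$cluster)
    tk <- tibble(comparison = rownames(tk), diff = tk$diff,
                 p_adjusted = tk$`p adj`)
    tibble(variable = "age", test = "anova", statistic = an$`F value`[1],
           df = an$Df[1], p_value = an$`Pr(>F)`[1],
           significant = an$`Pr(>F)`[1] <= alpha, note = NA_character_,
           posthoc = list(tk))
  }

  sex_row <- if (length(unique(gm$sex)) < 2) {
    inform("Variable 'sex' is constant; test skipped")
    tibble(variable = "sex", test = "skipped", statistic = NA_real_,
           df = NA_real_, p_value = NA_real_, significant = NA,
           note = "constant variable", posthoc = list(NULL))
  } else {
    ct <- suppressWarnings(chisq.test(table(grp, gm$sex), correct = FALSE))
    tibble(variable = "sex", test = "chi_squared",
           statistic = unname(ct$statistic), df = unname(ct$parameter),
           p_value = ct$p.value, significant = ct$p.value <= alpha,
           note = NA_character_, posthoc = list(NULL))
  }

  out <- bind_rows(rows, age_row, sex_row)
  class(out) <- c("dietshift_comparison", class(out))
  out
}
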