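#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diet solution into its per-food weight table
#'
#' @param x A `diet_solution`.
#' @param ... Unused.
#' @return Tibble with `food_id`, `group`, `exempt`, `w_rep`, `w_opt`, `rd`.
#' @method tidy diet_solution
#' @export
tidy.diet_solution <- function(x, ...) {
  if (x$status != "optimal") {
    abort("No weights to tidy: solution status is not optimal",
          class = "dietshift_validation_error")
  }
  x$weights
}

#' One-row summary of a diet solution
#'
#' @param x A `diet_solution`.
#' @param ... Unused.
#' @return One-row tibble with status, TRD, ARD, CO2eq, cost, energy and the
#'   food-change census.
#' @method glance diet_solution
#' @export
glance.diet_solution <- function(x, ...) {
  tibble(
    status = x$status,
    trd = x$trd,
    ard_percent = x$ard_percent,
    co2eq_g = x$co2eq_g %||% NA_real_,
    cost_sek = x$cost_sek %||% NA_real_,
    energy_kcal = x$energy_kcal %||% NA_real_,
    n_foods = if (is.null(x$weights)) NA_integer_ else nrow(x$weights),
    n_removed = length(x$removed %||% character(0)),
    n_reduced = length(x$reduced %||% character(0)),
    n_increased = length(x$increased %||% character(0)),
    n_active_constraints = if (is.null(x$active_constraints)) NA_integer_
                           else nrow(x$active_constraints)
  )
}

#' Tidy a clustering result into its label table
#'
#' @param x A `dietshift_clusters`.
#' @param ... Unused.
#' @return Tibble `person_id`, `cluster`.
#' @method tidy dietshift_clusters
#' @export
tidy.dietshift_clusters <- function(x, ...) x$labels

#' One-row summary of a clustering result
#'
#' @param x A `dietshift_clusters`.
#' @param ... Unused.
#' @return One-row tibble with `k`, the validity indices and the inversion
#'   flag.
#' @method glance dietshift_clusters
#' @export
glance.dietshift_clusters <- function(x, ...) {
  tibble(
    k = x$k, dunn = x$dunn,
    silhouette = x$extra_indices[["silhouette"]],
    calinski_harabasz = x$extra_indices[["calinski_harabasz"]],
    inversions = x$inversions
  )
}

#' Plot mean z-scored feature profiles per cluster
#'
#' @param object A `dietshift_clusters`.
#' @param features The feature matrix the clustering was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dietshift_clusters
#' @export
autoplot.dietshift_clusters <- function(object, features, ...) {
  m <- as.matrix(features)
  df <- as_tibble(m) |>
    mutate(person_id = rownames(m)) |>
    inner_join(object$labels, by = "person_id") |>
    tidyr::pivot_longer(cols = -c("person_id", "cluster"),
                        names_to = "variable", values_to = "z") |>
    group_by(.data$cluster, .data$variable) |>
    summarise(mean_z = mean(.data$z), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_z, y = .data$variable,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Mean z-scored intake (g/MJ)", y = NULL,
                  fill = "Cluster")
}
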