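#' Energy-adjusted food-group intakes
#'
#' Per-individual intake of every food group in g/MJ (grams per megajoule of
#' that individual's dietary energy), plus the whole-grain content column
#' (grams of whole grain per MJ, weighted by each food's whole-grain
#' fraction) and dietary CO2eq in g/MJ. This is the unscaled variable set the
#' cluster analysis and the post-hoc comparisons both work from.
#'
#' @param population A [survey_population()].
#' @return Tibble: `person_id`, one column per food group (g/MJ),
#'   `whole_grains` (g/MJ) and `co2eq` (g/MJ).
#' @export
group_intake_per_mj <- function(population) {
  en <- energy_intake(population)
  aug <- population$intakes |>
    left_join(select(population$foods, "food_id", "group",
                     "whole_grain_frac", "co2eq_g_per_g"), by = "food_id") |>
    left_join(select(en, "person_id", "energy_mj"), by = "person_id")
  by_group <- aug |>
    group_by(.data$person_id, .data$group) |>
    summarise(g_per_mj = sum(.data$intake_g_day) / .data$energy_mj[1],
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "g_per_mj",
                       values_fill = 0)
  extras <- aug |>
    group_by(.data$person_id) |>
    summarise(
      whole_grains = sum(.data$intake_g_day * .data$whole_grain_frac) /
        .data$energy_mj[1],
      co2eq = sum(.data$intake_g_day * .data$co2eq_g_per_g) /
        .data$energy_mj[1],
      .groups = "drop")
  by_group |> left_join(extras, by = "person_id")
}

#' Build the cluster feature matrix
#'
#' Food groups consumed by fewer than `prevalence` (default 75 %) of the
#' population are dropped to avoid clustering on structural zeros, except
#' for the groups in `exceptions` (by default Pulses and Nuts and seeds,
#' retained as indicators of climate-friendly, healthy eating regardless of
#' prevalence). Whole-grain g/MJ is appended as an extra variable. Every
#' retained column is then z-scored (mean 0, sd 1); a retained column with
#' zero variance is an error naming the column.
#'
#' @param population A [survey_population()].
#' @param exceptions Food groups retained regardless of prevalence.
#' @param prevalence Minimum fraction of individuals with positive group
#'   intake for the group to be retained.
#' @return A matrix (rows = individuals, named by `person_id`) of class
#'   `dietshift_features`, with attributes `retained_groups`, `scaling`
#'   (per-column mean and sd) and `raw` (the unscaled g/MJ matrix).
#' @export
build_features <- function(population,
                           exceptions = c("Pulses", "Nuts and seeds"),
                           prevalence = 0.75) {
  gm <- group_intake_per_mj(population)
  groups <- setdiff(names(gm), c("person_id", "whole_grains", "co2eq"))
  prev <- purrr::map_dbl(groups, function(g) mean(gm[[g]] > 0))
  retained <- groups[prev >= prevalence | groups %in% exceptions]
  cols <- c(retained, "whole_grains")
  raw <- as.matrix(gm[cols])
  rownames(raw) <- gm$person_id
  sds <- apply(raw, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Zero variance in retained column(s): ",
                 paste(cols[sds == 0], collapse = ", ")),
          class = "dietshift_validation_error")
  }
  mus <- colMeans(raw)
  scaled <- scale(raw, center = mus, scale = sds)
  attributes(scaled)$`scaled:center` <- NULL
  attributes(scaled)$`scaled:scale` <- NULL
  structure(scaled, retained_groups = retained,
            scaling = list(mean = mus, sd = sds), raw = raw,
            class = c("dietshift_features", "matrix", "array"))
}

#' Canberra distance between two feature vectors
#'
#' \deqn{d(x, y) = \frac{p}{p_{used}} \sum_{i:\,|x_i|+|y_i|>0}
#'   \frac{|x_i - y_i|}{|x_i| + |y_i|}}
#' Coordinates where both entries are zero are omitted and the sum rescaled
#' by the ratio of total to used coordinates (the convention of R's distance
#' machinery); the distance is 0 when every coordinate is omitted. Each term
#' is at most 1, so \eqn{d \le p}.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single nonnegative number.
#' @export
canberra_distance <- function(x, y) {
  if (length(x) != length(y)) {
    abort("canberra_distance requires equal-length vectors",
          class = "dietshift_validation_error")
  }
  den <- abs(x) + abs(y)
  used <- den > 0
  if (!any(used)) return(0)
  (length(x) / sum(used)) * sum(abs(x - y)[used] / den[used])
}

#' Canberra distance matrix
#'
#' All pairwise [canberra_distance()]s of the rows of a matrix, vectorised
#' column-by-column.
#'
#' @param mat Numeric matrix (rows = observations).
#' @return A `dist` object.
#' @export
canberra_dist <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); p <- ncol(mat)
  acc <- matrix(0, n, n)
  used <- matrix(0, n, n)
  for (j in seq_len(p)) {
    x <- mat[, j]
    num <- abs(outer(x, x, "-"))
    den <- outer(abs(x), abs(x), "+")
    ok <- den > 0
    term <- matrix(0, n, n)
    term[ok] <- num[ok] / den[ok]
    acc <- acc + term
    used <- used + ok
  }
  d <- matrix(0, n, n)
  pos <- used > 0
  d[pos] <- p * acc[pos] / used[pos]
  rownames(d) <- colnames(d) <- rownames(mat)
  as.dist(d)
}

#' Hierarchical clustering with Ward's method
#'
#' Agglomerates the given dissimilarities with the Lance-Williams update for
#' Ward's method applied to the dissimilarities as supplied (the `"ward.D"`
#' dialect, matching classic R workflows that fed Canberra distances straight
#' in; set `method = "ward.D2"` to square first). The tree is cut at `k`
#' clusters. Ward on non-Euclidean dissimilarities can produce inversions
#' (non-monotone merge heights); these are flagged, not fixed.
#'
#' @param d A `dist` object or symmetric matrix with zero diagonal.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param features Optional feature matrix for the extra validity indices
#'   (silhouette comes from the distances; Calinski-Harabasz needs
#'   coordinates and is `NA` without them).
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return An object of class `dietshift_clusters`: list with `linkage` (the
#'   `hclust` tree), `labels` (tibble `person_id`, `cluster`), `k`, `dunn`,
#'   `extra_indices` (silhouette, Calinski-Harabasz), `inversions` flag.
#' @export
ward_cluster <- function(d, k, features = NULL, method = "ward.D") {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-8) || any(diag(m) != 0)) {
      abort("Distance input must be symmetric with zero diagonal",
            class = "dietshift_validation_error")
    }
    d <- as.dist(m)
  }
  n <- attr(d, "Size")
  if (k < 2 || k > n) {
    abort("k must lie in [2, n]", class = "dietshift_validation_error")
  }
  tree <- hclust(d, method = method)
  cl <- cutree(tree, k = k)
  ids <- tree$labels %||% as.character(seq_len(n))
  labels <- tibble(person_id = ids, cluster = unname(cl))
  dn <- dunn_index(cl, d)
  sil <- if (k < n) {
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  } else NA_real_
  ch <- if (!is.null(features)) calinski_harabasz(as.matrix(features), cl) else NA_real_
  structure(
    list(linkage = tree, labels = labels, k = k, dunn = dn,
         extra_indices = c(silhouette = sil, calinski_harabasz = ch),
         inversions = is.unsorted(tree$height)),
    class = "dietshift_clusters"
  )
}

#' @export
print.dietshift_clusters <- function(x, ...) {
  cat("<dietshift_clusters> k =", x$k, "\n")
  print(table(cluster = x$labels$cluster))
  cat(sprintf("  Dunn %.4g | silhouette %.4g | Calinski-Harabasz %.4g%s\n",
              x$dunn, x$extra_indices[["silhouette"]],
              x$extra_indices[["calinski_harabasz"]],
              if (x$inversions) " | tree has inversions" else ""))
  invisible(x)
}

#' Dunn index of a partition
#'
#' The ratio of the smallest distance between observations in different
#' clusters to the largest distance between observations in the same
#' cluster; `Inf` when every cluster is a singleton (zero intra-cluster
#' spread).
#'
#' @param labels Cluster assignment (vector, one entry per observation).
#' @param d `dist` object or symmetric distance matrix over the same
#'   observations.
#' @return A single value in `(0, Inf]`.
#' @export
dunn_index <- function(labels, d) {
  m <- as.matrix(d)
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2) {
    abort("Dunn index needs at least two clusters",
          class = "dietshift_validation_error")
  }
  same <- outer(labels, labels, "==")
  off <- upper.tri(m)
  intra <- m[off & same]
  inter <- m[off & !same]
  max_intra <- if (length(intra) == 0) 0 else max(intra)
  min_inter <- min(inter)
  if (max_intra == 0) return(Inf)
  min_inter / max_intra
}

# Calinski-Harabasz pseudo-F from coordinates: between-cluster over
# within-cluster dispersion, (B/(k-1)) / (W/(n-k)).
calinski_harabasz <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(X)
  W <- 0; B <- 0
  for (cl in unique(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    ci <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, ci)^2)
    B <- B + nrow(Xi) * sum((ci - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Choose the number of clusters by a three-index vote
#'
#' For each candidate `k`, cuts the Ward tree and computes the Dunn index,
#' the mean silhouette width and the Calinski-Harabasz pseudo-F. Each index
#' votes for its argmax `k`; the recommended `k` is the majority vote, ties
#' broken toward the smallest voted `k`.
#'
#' @param features Feature matrix (e.g. from [build_features()]).
#' @param k_range Candidate cluster counts.
#' @param d Optional precomputed `dist`; default Canberra distances on
#'   `features`.
#' @param method Linkage dialect passed to [ward_cluster()].
#' @return List with `recommended_k` and `indices` (tibble of per-k values).
#' @export
select_k <- function(features, k_range = 2:6, d = NULL, method = "ward.D") {
  features <- as.matrix(features)
  d <- d %||% canberra_dist(features)
  tab <- purrr::map_dfr(k_range, function(k) {
    res <- ward_cluster(d, k, features = features, method = method)
    tibble(k = k, dunn = res$dunn,
           silhouette = res$extra_indices[["silhouette"]],
           calinski_harabasz = res$extra_indices[["calinski_harabasz"]])
  })
  votes <- c(tab$k[which.max(tab$dunn)],
             tab$k[which.max(tab$silhouette)],
             tab$k[which.max(tab$calinski_harabasz)])
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  list(recommended_k = min(winners), indices = tab, votes = votes)
}
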