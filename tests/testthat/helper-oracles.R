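# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately share no code with R/.

# Canberra distance, literal double loop over coordinates.
bf_canberra <- function(x, y) {
  s <- 0; used <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) {
      s <- s + abs(x[i] - y[i]) / den
      used <- used + 1
    }
  }
  if (used == 0) return(0)
  length(x) / used * s
}

# Dunn index, double loop over all pairs.
bf_dunn <- function(labels, m) {
  n <- nrow(m)
  min_inter <- Inf; max_intra <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) {
      max_intra <- max(max_intra, m[i, j])
    } else {
      min_inter <- min(min_inter, m[i, j])
    }
  }
  if (max_intra == 0) return(Inf)
  min_inter / max_intra
}

# Naive Ward agglomeration via the Lance-Williams recurrence applied to the
# dissimilarities as given (the "ward.D" dialect); returns the partition at
# k clusters.
bf_ward_partition <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- D
  while (length(members) > k) {
    m <- length(members)
    bd <- Inf; bi <- NA; bj <- NA
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (d[i, j] < bd) { bd <- d[i, j]; bi <- i; bj <- j }
    }
    newd <- rep(NA_real_, m)
    for (h in seq_len(m)) {
      if (h == bi || h == bj) next
      newd[h] <- ((sizes[bi] + sizes[h]) * d[bi, h] +
                  (sizes[bj] + sizes[h]) * d[bj, h] -
                  sizes[h] * d[bi, bj]) /
                 (sizes[bi] + sizes[bj] + sizes[h])
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    d[bi, ] <- newd; d[, bi] <- newd
    members[[bj]] <- NULL
    sizes <- sizes[-bj]
    d <- d[-bj, -bj, drop = FALSE]
  }
  labels <- integer(n)
  for (c in seq_along(members)) labels[members[[c]]] <- c
  labels
}

# Greedy variance-minimising agglomeration from coordinates: at each step
# merge the pair of clusters whose union increases total within-cluster SSE
# the least. Equivalent to Ward ("ward.D") on squared Euclidean distances.
bf_sse_partition <- function(X, k) {
  n <- nrow(X)
  members <- as.list(seq_len(n))
  sse <- function(idx) {
    Xi <- X[idx, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }
  while (length(members) > k) {
    m <- length(members)
    bd <- Inf; bi <- NA; bj <- NA
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      inc <- sse(c(members[[i]], members[[j]])) -
        sse(members[[i]]) - sse(members[[j]])
      if (inc < bd) { bd <- inc; bi <- i; bj <- j }
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  labels <- integer(n)
  for (c in seq_along(members)) labels[members[[c]]] <- c
  labels
}

# Two partitions agree up to label renaming.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Adjusted Rand index between two labellings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expect <- si * sj / choose(n, 2)
  (sij - expect) / ((si + sj) / 2 - expect)
}

# Grid-search oracle for the diet LP on instances with at most 3 foods.
# The energy equality eliminates the last food's weight; the remaining
# weights are enumerated on a grid over the bound box (refined around the
# coarse optimum for 3-food instances). Returns the minimum sum of |RD|
# over feasible grid points, or Inf if none is feasible.
grid_oracle <- function(model, step_frac = 1e-3) {
  w_rep <- model$w_rep
  F <- length(w_rep)
  stopifnot(F <= 3)
  e <- model$foods$energy_kcal_per_g
  E0 <- model$energy_kcal
  ub <- ifelse(model$exempt, 10 * w_rep, (1 + model$max_increase_rd) * w_rep)
  ineq <- model$constraints$id != "energy"
  C <- model$C[ineq, , drop = FALSE]
  dirs <- model$constraints$direction[ineq]
  lims <- model$constraints$limit[ineq]
  feasible <- function(W) { # W: matrix, rows = candidate diets
    ok <- rep(TRUE, nrow(W))
    if (nrow(C) > 0) {
      ach <- W %*% t(C)
      for (r in seq_len(nrow(C))) {
        tolr <- 1e-9 * max(1, abs(lims[r]))
        ok <- ok & if (dirs[r] == "ge") ach[, r] >= lims[r] - tolr
                   else ach[, r] <= lims[r] + tolr
      }
    }
    ok
  }
  objective <- function(W) rowSums(abs(sweep(W, 2, w_rep) ) /
                                     rep(w_rep, each = nrow(W)))
  solve_last <- function(Wfree) {
    wlast <- (E0 - as.vector(Wfree %*% e[-F])) / e[F]
    W <- cbind(Wfree, wlast)
    keep <- wlast >= -1e-12 & wlast <= ub[F] + 1e-12
    W[keep, , drop = FALSE]
  }
  best_over <- function(grids) {
    Wfree <- as.matrix(expand.grid(grids))
    W <- solve_last(Wfree)
    if (nrow(W) == 0) return(Inf)
    W <- W[feasible(W), , drop = FALSE]
    if (nrow(W) == 0) return(Inf)
    min(objective(W))
  }
  if (F == 1) {
    W <- matrix(E0 / e, 1, 1)
    if (W[1] < -1e-12 || W[1] > ub[1] + 1e-9 || !feasible(W)) return(Inf)
    return(objective(W))
  }
  if (F == 2) {
    return(best_over(list(seq(0, ub[1], by = step_frac * w_rep[1]))))
  }
  # F == 3: coarse pass then local refinement (the objective is convex and
  # the feasible set is a polytope, so refining near the coarse optimum is
  # sound)
  coarse <- lapply(1:2, function(i) seq(0, ub[i], length.out = 121))
  Wfree <- as.matrix(expand.grid(coarse))
  W <- solve_last(Wfree)
  W <- W[feasible(W), , drop = FALSE]
  if (nrow(W) == 0) return(Inf)
  centre <- W[which.min(objective(W)), 1:2]
  span <- sapply(1:2, function(i) ub[i] / 120)
  fine <- lapply(1:2, function(i) {
    g <- seq(max(0, centre[i] - 2 * span[i]),
             min(ub[i], centre[i] + 2 * span[i]), by = step_frac * w_rep[i])
    unique(c(g, centre[i]))
  })
  best_over(fine)
}
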