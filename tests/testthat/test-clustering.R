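test_that("canberra distance matches its stated form", {
  expect_equal(canberra_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(canberra_distance(c(1, 0), c(0, 1)), 2)
  # 0/0 coordinate omitted, sum rescaled by p / p_used
  expect_equal(canberra_distance(c(1, 2, 0), c(3, 2, 0)), 0.75)
  expect_equal(canberra_distance(c(0, 0), c(0, 0)), 0)
  expect_error(canberra_distance(1:3, 1:2),
               class = "dietshift_validation_error")
})

test_that("canberra is a semimetric bounded by the dimension", {
  withr::local_seed(42)
  for (rep in 1:20) {
    p <- sample(2:6, 1)
    x <- round(rnorm(p), 2); y <- round(rnorm(p), 2)
    # some structural zeros so the omission rule engages
    x[sample(p, 1)] <- 0; y[sample(p, 1)] <- 0
    dxy <- canberra_distance(x, y)
    expect_equal(dxy, bf_canberra(x, y))
    expect_equal(dxy, canberra_distance(y, x))
    expect_gte(dxy, 0)
    expect_lte(dxy, p + 1e-12)
    expect_equal(canberra_distance(x, x), 0)
  }
})

test_that("canberra distance matrix equals the pairwise brute force", {
  withr::local_seed(1)
  m <- matrix(rnorm(8 * 5), 8, 5)
  m[sample(length(m), 10)] <- 0
  d <- as.matrix(canberra_dist(m))
  for (i in 1:8) for (j in 1:8) {
    expect_equal(d[i, j], bf_canberra(m[i, ], m[j, ]), tolerance = 1e-12)
  }
})

test_that("ward clustering agrees with direct Lance-Williams agglomeration", {
  withr::local_seed(7)
  # two points: one merge, singletons at k = 2
  d2 <- as.dist(matrix(c(0, 3, 3, 0), 2))
  cl2 <- ward_cluster(d2, 2)
  expect_equal(sort(unique(tidy(cl2)$cluster)), 1:2)

  # two well-separated pairs
  x4 <- c(0, 0.1, 10, 10.1)
  d4 <- dist(x4)
  cl4 <- tidy(ward_cluster(d4, 2))$cluster
  expect_true(same_partition(cl4, c(1, 1, 2, 2)))

  # random 6-point matrices against the exhaustive oracle, several cuts
  for (rep in 1:5) {
    x <- matrix(rnorm(12), 6, 2)
    D <- canberra_dist(abs(x))
    for (k in 2:4) {
      ours <- tidy(ward_cluster(D, k))$cluster
      expect_true(same_partition(ours, bf_ward_partition(D, k)))
    }
  }
})

test_that("ward on squared Euclidean distances minimises within-cluster variance", {
  withr::local_seed(11)
  for (rep in 1:3) {
    X <- matrix(rnorm(16), 8, 2)
    Dsq <- dist(X)^2
    for (k in c(2, 3)) {
      ours <- tidy(ward_cluster(Dsq, k))$cluster
      expect_true(same_partition(ours, bf_sse_partition(X, k)))
    }
  }
})

test_that("cluster labels are invariant to row permutation", {
  gen <- default_gen()
  feats <- build_features(gen$population)
  m <- as.matrix(feats)
  lab1 <- tidy(ward_cluster(canberra_dist(m), 3))
  perm <- withr::with_seed(5, sample(nrow(m)))
  lab2 <- tidy(ward_cluster(canberra_dist(m[perm, ]), 3))
  merged <- dplyr::inner_join(lab1, lab2, by = "person_id")
  expect_true(same_partition(merged$cluster.x, merged$cluster.y))
})

test_that("ward_cluster validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_cluster(bad, 2), class = "dietshift_validation_error")
  expect_error(ward_cluster(dist(1:5), 1), class = "dietshift_validation_error")
})

test_that("dunn index equals the double-loop brute force", {
  # two singletons: zero intra-cluster spread
  expect_equal(dunn_index(c(1, 2), matrix(c(0, 5, 5, 0), 2)), Inf)
  # two tight pairs far apart
  m <- as.matrix(dist(c(0, 1, 4, 5)))
  expect_equal(dunn_index(c(1, 1, 2, 2), m), 3)
  expect_error(dunn_index(c(1, 1), matrix(0, 2, 2)),
               class = "dietshift_validation_error")
  withr::local_seed(9)
  for (rep in 1:5) {
    X <- matrix(rnorm(16), 8, 2)
    m <- as.matrix(dist(X))
    lab <- sample(1:3, 8, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(dunn_index(lab, m), bf_dunn(lab, m))
  }
})

test_that("prevalence filter drops rare groups except the declared exceptions", {
  # 100 individuals; group B consumed by 74 %, Pulses by 10 %
  foods <- toy_foods(c("a", "b", "p"),
                     group = c("Vegetables", "Dairy", "Pulses"), energy = 1,
                     wg = c(0.3, 0, 0))
  n <- 100
  m <- cbind(rep(100, n),
             c(rep(50, 74), rep(0, 26)),
             c(rep(20, 10), rep(0, 90)))
  pop <- toy_population(foods, m)
  feats <- build_features(pop)
  expect_false("Dairy" %in% attr(feats, "retained_groups"))
  expect_true("Pulses" %in% attr(feats, "retained_groups"))
  # at exactly 75 % the group is kept
  m75 <- cbind(rep(100, n), c(rep(50, 75), rep(0, 25)), rep(10, n))
  feats75 <- build_features(toy_population(foods, m75))
  expect_true("Dairy" %in% attr(feats75, "retained_groups"))
})

test_that("features are g/MJ before scaling and z-scored after", {
  foods <- toy_foods(c("a", "b"), group = "Vegetables", energy = c(2, 1),
                     wg = c(0, 0.5))
  m <- rbind(c(100, 0), c(50, 30))
  pop <- toy_population(foods, m)
  feats <- build_features(pop)
  raw <- attr(feats, "raw")
  # person 1: 100 g/day at 2 kcal/g = 200 kcal = 0.8368 MJ
  expect_equal(raw[1, "Vegetables"], 100 / 0.8368, tolerance = 1e-12)
  expect_equal(colMeans(as.matrix(feats)), c(Vegetables = 0, whole_grains = 0),
               tolerance = 1e-12)

  # a retained column with no variation is an error naming it
  pop0 <- toy_population(toy_foods("a", energy = 1), rbind(100, 100))
  expect_error(build_features(pop0), "whole_grains",
               class = "dietshift_validation_error")
})

test_that("select_k finds planted structure and breaks ties toward small k", {
  # two obvious blobs
  withr::local_seed(2)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10))
  X <- abs(X)
  sk <- select_k(X, 2:5)
  expect_equal(sk$recommended_k, 2)

  # synthetic three-archetype default
  res <- default_results()
  sk3 <- select_k(res$features, 2:6)
  expect_equal(sk3$recommended_k, 3)

  # the recommendation follows the stated vote rule, recomputed independently
  for (sk in list(sk, sk3)) {
    tab <- sk$indices
    votes <- c(tab$k[which.max(tab$dunn)], tab$k[which.max(tab$silhouette)],
               tab$k[which.max(tab$calinski_harabasz)])
    cnt <- table(votes)
    expect_equal(sk$recommended_k,
                 min(as.integer(names(cnt)[cnt == max(cnt)])))
  }
})
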