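euclid_cfg <- function(...) metric_config(high_metric = "euclidean", ...)

test_that("co-KNN accuracy is 1 for identical spaces and k = n - 1", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  expect_equal(knn_accuracy(X, X, euclid_cfg(knn_k = 3)), 1)

  Y <- matrix(rnorm(40), 20, 2)
  expect_equal(knn_accuracy(X, Y, euclid_cfg(knn_k = 19)), 1)
  expect_error(knn_accuracy(X, Y, euclid_cfg(knn_k = 20)), "more than")
})

test_that("co-KNN accuracy equals the brute-force oracle, incl. the 1-D flip case", {
  # 1-D instance where every nearest neighbour flips between spaces
  H <- cbind(c(0, 1, 10)); L <- cbind(c(0, 10, 1))
  o <- oracle_knn_accuracy(H, L, 1, "euclidean", "euclidean")
  expect_equal(knn_accuracy(H, L, euclid_cfg(knn_k = 1)), o)
  expect_equal(o, 0)

  set.seed(5)
  for (i in 1:30) {
    n <- sample(4:8, 1); k <- sample(1:3, 1)
    H <- matrix(rnorm(n * 2) + 2, n)   # offset keeps cosine well-defined
    L <- matrix(rnorm(n * 2), n)
    expect_equal(knn_accuracy(H, L, metric_config(knn_k = k)),
                 oracle_knn_accuracy(H, L, k, "cosine", "euclidean"))
  }
})

test_that("triplet accuracy: isometry gives 1, degenerate low space gives 0.5", {
  set.seed(6)
  X <- matrix(rnorm(30), 15, 2)
  rot <- qr.Q(qr(matrix(rnorm(4), 2)))
  expect_equal(random_triplet_accuracy(X, X %*% rot + 3, euclid_cfg()), 1)
  expect_equal(random_triplet_accuracy(X, matrix(1, 15, 2), euclid_cfg()), 0.5)
  expect_error(random_triplet_accuracy(X[1:2, ], X[1:2, ], euclid_cfg()),
               "at least 3")
})

test_that("exhaustive triplet accuracy equals full enumeration oracle", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    H <- matrix(rnorm(n * 2) + 2, n)
    L <- matrix(rnorm(n * 2), n)
    expect_equal(random_triplet_accuracy(H, L, metric_config(), exhaustive = TRUE),
                 oracle_triplet_accuracy(H, L, "cosine", "euclidean"))
  }
})

test_that("Spearman of pairwise distances respects monotone transforms", {
  set.seed(8)
  X <- matrix(rnorm(24), 12, 2)
  expect_equal(spearman_pairwise(X, X, euclid_cfg()), 1)

  d <- condensed_pairwise(X)
  up <- d; up[] <- exp(as.vector(d))          # strictly increasing transform
  down <- d; down[] <- exp(-as.vector(d))     # strictly decreasing
  expect_equal(spearman_pairwise(d, up), 1)
  expect_equal(spearman_pairwise(d, down), -1)

  const <- d; const[] <- 1
  expect_error(spearman_pairwise(d, const), "constant")
})

test_that("centroid distance correlation matches hand ranks and isometry", {
  # 3 singleton classes: centroid distances (1,2,3) vs (3,1,2) -> -0.5
  high <- cbind(c(0, 1, -2)); low <- cbind(c(0, 3, 1))
  expect_equal(
    centroid_distance_correlation(high, low, 1:3, euclid_cfg()), -0.5)

  set.seed(9)
  X <- matrix(rnorm(80), 40, 2)
  labs <- rep(1:4, each = 10)
  rot <- qr.Q(qr(matrix(rnorm(4), 2)))
  expect_equal(
    centroid_distance_correlation(X, X %*% rot + 1, labs, euclid_cfg()), 1)

  expect_error(centroid_distance_correlation(X, X, rep(1:2, 20), euclid_cfg()),
               "3 classes")
})

test_that("mean Dunn index matches the two-cluster hand instance", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labs <- c(1, 1, 2, 2)
  expect_equal(mean_dunn_index(pts, labs), (20 + 2 * sqrt(101)) / 4,
               tolerance = 1e-12)

  expect_error(mean_dunn_index(pts, c(1, 1, 2, 3)), "singleton")
  expect_error(mean_dunn_index(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                               labs), "coincident")
})

test_that("mean Dunn of shuffled labels on symmetric blobs sits near 1", {
  set.seed(10)
  pts <- rbind(matrix(rnorm(120, 0, 1), 60), matrix(rnorm(120, 8, 1), 60))
  ratios <- replicate(20, mean_dunn_index(pts, sample(rep(1:2, 60))))
  expect_lt(abs(median(ratios) - 1), 0.1)
  # and the true labelling is strongly separated
  expect_gt(mean_dunn_index(pts, rep(1:2, each = 60)), 2)
})

test_that("metrics restrict to a shared subsample when configured", {
  set.seed(11)
  H <- matrix(rnorm(60) + 2, 30, 2)
  L <- matrix(rnorm(60), 30, 2)
  sub <- c(2, 5, 9, 14, 20, 28)
  cfg <- metric_config(knn_k = 2, subsample = sub)
  plain <- metric_config(knn_k = 2)
  expect_equal(knn_accuracy(H, L, cfg),
               knn_accuracy(H[sub, ], L[sub, ], plain))
  expect_equal(spearman_pairwise(H, L, cfg),
               spearman_pairwise(H[sub, ], L[sub, ], plain))
})
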