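test_that("condensed pairwise distances match hand values in both metrics", {
  expect_equal(as.vector(condensed_pairwise(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(as.vector(condensed_pairwise(rbind(c(1, 0), c(0, 1)), "cosine")), 1)
  expect_equal(as.vector(condensed_pairwise(rbind(c(1, 1), c(2, 2)), "cosine")), 0)
  expect_error(condensed_pairwise(rbind(c(0, 0), c(1, 1)), "cosine"),
               "all-zero row.*1")
})

test_that("average linkage reproduces the collinear hand example", {
  d <- condensed_pairwise(cbind(c(0, 1, 5)))
  tree <- average_linkage(d)
  expect_equal(tree$height, c(1, 4.5)) # {0,1} at 1, then mean(5, 4) = 4.5
  expect_identical(tree$n, 3L)

  two <- average_linkage(condensed_pairwise(cbind(c(2, 7))))
  expect_equal(two$height, 5)

  tri <- average_linkage(stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)))
  expect_equal(tri$height, c(1, 1)) # equilateral: both merges at height 1
})

test_that("linkage heights are monotone on random instances", {
  set.seed(42)
  for (i in 1:25) {
    m <- sample(3:15, 1)
    X <- matrix(rnorm(m * 3), m)
    tree <- average_linkage(condensed_pairwise(X))
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("cophenetic distances match the traversal oracle on hand cases", {
  tree <- average_linkage(condensed_pairwise(cbind(c(0, 1, 5))))
  coph <- cophenetic_distances(tree)
  expect_equal(as.vector(coph), c(1, 4.5, 4.5)) # pairs (1,2), (1,3), (2,3)
  expect_equal(as.vector(coph), as.vector(oracle_cophenetic(tree)))

  d2 <- condensed_pairwise(cbind(c(2, 7)))
  expect_equal(as.vector(cophenetic_distances(average_linkage(d2))),
               as.vector(d2))
})

test_that("UPGMA reproduces an ultrametric input exactly", {
  set.seed(8)
  for (i in 1:10) {
    X <- matrix(rnorm(8 * 2), 8)
    ultra <- cophenetic_distances(average_linkage(condensed_pairwise(X)))
    again <- cophenetic_distances(average_linkage(ultra))
    expect_equal(as.vector(again), as.vector(ultra), tolerance = 1e-12)
  }
})

test_that("NMI handles analytic and degenerate cases by convention", {
  x <- c(1, 1, 2, 3, 3)
  expect_equal(normalized_mutual_information(x, x * 10), 1)
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(5, 6, 5, 6)), 0)
  expect_equal(normalized_mutual_information(c(1, 1, 2, 3), c(9, 9, 8, 8)), 0.8)
  # symmetry
  set.seed(1)
  a <- sample(1:3, 20, TRUE); b <- sample(1:4, 20, TRUE)
  expect_equal(normalized_mutual_information(a, b),
               normalized_mutual_information(b, a))
  # degenerate conventions
  expect_equal(normalized_mutual_information(rep(1, 4), rep(2, 4)), 1)
  expect_equal(normalized_mutual_information(rep(1, 4), c(1, 2, 3, 4)), 0)
  expect_error(normalized_mutual_information(1:3, 1:4), "length")
})

test_that("representative sampling returns k = n/100 nearest-to-centroid pixels", {
  set.seed(3)
  emb <- matrix(rnorm(300 * 3), 300)
  idx <- sample_representatives(emb, dci_params(kmeans_seed = 5))
  expect_identical(length(idx), 3L)
  expect_true(all(idx %in% 1:300))

  # three well-separated blobs: exactly one representative per blob
  blobs <- rbind(matrix(rnorm(200, 0, 0.1), 100),
                 matrix(rnorm(200, 10, 0.1), 100),
                 matrix(rnorm(200, 30, 0.1), 100))
  idx3 <- sample_representatives(blobs, dci_params(kmeans_seed = 5))
  expect_identical(sort(findInterval(idx3, c(101, 201))), 0:2)

  expect_error(sample_representatives(matrix(rnorm(4), 2), dci_params()),
               "at least 3")
  expect_identical(sample_representatives(emb, dci_params(kmeans_seed = 5)),
                   idx) # deterministic
})

test_that("DCI is invariant under isometries of the embedding at fixed indices", {
  cube <- small_cube()
  set.seed(21)
  emb <- matrix(rnorm(n_pixels(cube) * 3), ncol = 3)
  idx <- sample_representatives(emb, dci_params())
  base <- dci(cube, emb, indices = idx)$score
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))       # random orthogonal matrix
  moved <- emb %*% rot + matrix(c(5, -2, 1), n_pixels(cube), 3, byrow = TRUE)
  expect_equal(dci(cube, moved, indices = idx)$score, base, tolerance = 1e-8)
})

test_that("DCI is invariant under increasing transforms of a cophenetic vector", {
  cube <- small_cube()
  set.seed(22)
  emb <- matrix(rnorm(n_pixels(cube) * 3), ncol = 3)
  r <- dci(cube, emb)
  warped <- r$coph_low
  warped[] <- exp(as.vector(r$coph_low))     # strictly increasing, keeps ties
  expect_equal(normalized_mutual_information(r$coph_high, warped), r$score)
})

test_that("DCI results carry provenance and stay within [0, 1]", {
  cube <- small_cube()
  set.seed(23)
  emb <- matrix(rnorm(n_pixels(cube) * 3), ncol = 3)
  r <- dci(cube, emb)
  expect_s3_class(r, "dci_result")
  expect_true(r$score >= 0 && r$score <= 1)
  m <- length(r$sample_indices)
  expect_identical(length(as.vector(r$coph_high)), m * (m - 1L) %/% 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_dci_json(r, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$score, r$score)
  expect_equal(back$sample_indices, r$sample_indices)
})

test_that("misaligned cube and embedding are rejected", {
  cube <- small_cube()
  expect_error(dci(cube, matrix(0, 5, 3)), "not aligned")
})
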