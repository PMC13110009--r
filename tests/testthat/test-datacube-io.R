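tiny_cube <- function(n = 4L, nc = 10L, labels = NULL) {
  set.seed(11)
  msi_cube(matrix(runif(n * nc), n, nc), seq(100, 100 + nc - 1),
           cbind(x = rep(1:2, length.out = n),
                 y = rep(1:2, each = 2, length.out = n)),
           c(2L, 2L), labels)
}

test_that("cube constructor enforces its invariants", {
  expect_error(msi_cube(matrix(1, 2, 3), c(3, 2, 1), cbind(1:2, 1), c(2, 1)),
               "strictly increasing")
  expect_error(msi_cube(matrix(1, 2, 3), 1:2, cbind(1:2, 1), c(2, 1)),
               "mz axis")
  expect_error(msi_cube(matrix(1, 2, 3), 1:3, cbind(c(1, 1), c(1, 1)), c(2, 1)),
               "unique")
  expect_error(msi_cube(matrix(1, 2, 3), 1:3, cbind(1:2, c(1, 5)), c(2, 1)),
               "outside mask_shape")
})

test_that("imzML round trip preserves the cube to float precision", {
  cube <- tiny_cube()
  path <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(cube, path)
  back <- read_imzml(path)
  expect_equal(back$intensities, cube$intensities, tolerance = 1e-12)
  expect_equal(back$mz, cube$mz, tolerance = 1e-12)
  expect_equal(back$coords, cube$coords)
  expect_identical(n_pixels(back), 4L)
  expect_identical(n_channels(back), 10L)
})

test_that("processed-mode imzML and missing ibd are rejected with clear errors", {
  cube <- tiny_cube()
  path <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(cube, path)
  # flip the mode accession to processed
  txt <- readLines(path)
  writeLines(gsub("IMS:1000030", "IMS:1000031", txt), path)
  expect_error(read_imzml(path), "processed")

  path2 <- withr::local_tempfile(fileext = ".imzML")
  write_imzml(cube, path2)
  file.remove(sub("\\.imzML$", ".ibd", path2))
  expect_error(read_imzml(path2), "missing binary companion")
})

test_that("native container round trip is bit-exact, with and without labels", {
  for (labels in list(NULL, c(1L, 1L, 2L, 0L))) {
    cube <- tiny_cube(labels = labels)
    path <- withr::local_tempfile()
    write_native(cube, path)
    back <- read_native(path)
    expect_identical(back$intensities, cube$intensities)
    expect_identical(back$mz, cube$mz)
    expect_identical(back$coords, cube$coords)
    expect_identical(back$region_labels, cube$region_labels)
  }
})

test_that("corrupt or truncated native containers raise integrity errors", {
  cube <- tiny_cube()
  path <- withr::local_tempfile()
  write_native(cube, path)
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[seq_len(length(raw) - 16L)], path)
  expect_error(read_native(path), "integrity")

  bad <- withr::local_tempfile()
  writeBin(charToRaw("not a cube at all"), bad)
  expect_error(read_native(bad), "integrity")
})

test_that("embedding CSV round trip keeps coordinates", {
  cube <- tiny_cube()
  emb <- msi_embedding(matrix(rnorm(12), 4, 3), list(algorithm = "tsne"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedding_csv(emb, cube, path)
  back <- read_embedding_csv(path)
  expect_equal(unname(back$coordinates), unname(emb$coordinates),
               tolerance = 1e-12)
})

test_that("rebin interpolates exactly on constant and linear spectra", {
  mz <- c(100, 100.3, 100.7, 101)
  const <- msi_cube(matrix(3, 2, 4), mz, cbind(1:2, c(1L, 1L)), c(2L, 1L))
  rb <- rebin(const, 0.001)
  expect_equal(n_channels(rb), 1001L)  # floor(1 / 0.001) + 1
  expect_true(all(abs(rb$intensities - 3) < 1e-12))

  lin <- msi_cube(rbind(2 * mz + 1, 2 * mz + 1), mz,
                  cbind(1:2, c(1L, 1L)), c(2L, 1L))
  rb2 <- rebin(lin, 0.25)
  expect_equal(rb2$intensities[1, ], 2 * rb2$mz + 1, tolerance = 1e-12)
})

test_that("rebin is idempotent on an already-uniform grid and validates width", {
  mz <- seq(100, 102, by = 0.5)
  cube <- msi_cube(matrix(runif(10), 2, 5), mz, cbind(1:2, c(1L, 1L)),
                   c(2L, 1L))
  rb <- rebin(cube, 0.5)
  expect_equal(rb$intensities, cube$intensities, tolerance = 1e-12)
  expect_equal(rb$mz, cube$mz)
  expect_error(rebin(cube, 10), "wider than")
})

test_that("apply_roi restricts pixels and refuses an empty result", {
  cube <- tiny_cube(labels = c(1L, 1L, 2L, 2L))
  expect_identical(apply_roi(cube, rep(TRUE, 4))$intensities, cube$intensities)
  half <- apply_roi(cube, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(n_pixels(half), 2L)
  expect_identical(half$mz, cube$mz)
  expect_identical(half$region_labels, c(1L, 1L))
  expect_error(apply_roi(cube, rep(FALSE, 4)), "no pixels")
})

test_that("region mean spectra match hand arithmetic and the weighted-mean identity", {
  cube <- msi_cube(matrix(c(2, 4, 9, 20, 40, 90), 3, 2), c(100, 200),
                   cbind(1:3, rep(1L, 3)), c(3L, 1L), c(1L, 1L, 2L))
  ms <- region_mean_spectra(cube)
  expect_equal(unname(ms$region["1", ]), c(3, 30))
  expect_equal(unname(ms$region["2", ]), c(9, 90))
  expect_equal(unname(ms$global), c(5, 50))

  big <- desk_cube()
  msb <- region_mean_spectra(big)
  lhs <- colSums(msb$region * as.vector(msb$n))
  expect_equal(lhs, msb$global * sum(msb$n), tolerance = 1e-12)

  expect_error(region_mean_spectra(tiny_cube()), "labels")
})
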