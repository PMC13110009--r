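test_that("region masks partition the elliptical foreground deterministically", {
  m1 <- generate_region_mask(c(10L, 10L), 1L, seed = 3L)
  expect_true(all(m1[m1 > 0] == 1L))
  expect_gt(sum(m1 > 0), 0)

  expect_identical(generate_region_mask(c(30L, 20L), 5L, seed = 9L),
                   generate_region_mask(c(30L, 20L), 5L, seed = 9L))

  big <- generate_region_mask(c(152L, 307L), 8L, seed = 1L)
  sizes <- table(big[big > 0])
  expect_identical(length(sizes), 8L)
  expect_true(all(sizes > 0))
  expect_identical(sum(sizes), sum(big > 0))
})

test_that("zero-noise cubes reproduce the region templates exactly", {
  spec <- desk_spec(noise_cv = 0)
  cube <- synthesize_cube(spec)
  ms <- region_mean_spectra(cube)
  for (r in sort(unique(cube$region_labels))) {
    rows <- cube$intensities[cube$region_labels == r, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, ms$region[as.character(r), ]))), 0)
  }
})

test_that("channel count follows the species x adduct x isotope layout", {
  spec <- synthetic_spec(grid = c(12L, 12L), n_regions = 1L,
                         species_per_region = 1L, n_matrix_peaks = 0L,
                         isotope_peaks = 2L, seed = 2L)
  expect_identical(n_channels(synthesize_cube(spec)), 6L) # 1 x 3 adducts x 2 isotopes
})

test_that("noisy region means converge to the templates (CLT bound)", {
  cube <- desk_cube()
  tmpl <- region_mean_spectra(synthesize_cube(desk_spec(noise_cv = 0)))$region
  ms <- region_mean_spectra(cube)
  cv <- desk_spec()$noise_cv
  for (r in rownames(ms$region)) {
    n_r <- ms$n[[r]]
    if (n_r < 200) next
    se <- cv * tmpl[r, ] / sqrt(n_r)
    expect_true(all(abs(ms$region[r, ] - tmpl[r, ]) <= 5 * se))
  }
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- synthesize_cube(desk_spec())
  b <- synthesize_cube(desk_spec())
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$region_labels, b$region_labels)
})

test_that("homogenize is the identity at s = 0 and scales linearly", {
  cube <- small_cube()
  expect_equal(homogenize(cube, 0)$intensities, cube$intensities)

  # positive-scalar homogeneity
  h1 <- homogenize(cube, 0.6)
  scaled <- msi_cube(2.5 * cube$intensities, cube$mz, cube$coords,
                     cube$mask_shape, cube$region_labels)
  h2 <- homogenize(scaled, 0.6)
  expect_equal(h2$intensities, 2.5 * h1$intensities, tolerance = 1e-12)
})

test_that("homogenize can produce negatives, and clipping is optional", {
  cube <- small_cube()
  h <- homogenize(cube, 0.9)
  expect_true(any(h$intensities < 0)) # formula fidelity: no silent clipping
  expect_true(all(homogenize(cube, 0.9, clip = TRUE)$intensities >= 0))
  unlabelled <- msi_cube(cube$intensities, cube$mz, cube$coords,
                         cube$mask_shape)
  expect_error(homogenize(unlabelled, 0.5), "labels")
})

test_that("disparate bootstrap appends exact duplicates after the original block", {
  cube <- small_cube()
  n0 <- n_pixels(cube)
  out <- make_disparate(cube, region_id = 2L, n_bootstrap = 100L, seed = 5L)
  expect_identical(n_pixels(out), n0 + 100L)
  expect_identical(out$intensities[seq_len(n0), ], cube$intensities)
  expect_identical(out$region_labels[(n0 + 1):(n0 + 100)], rep(2L, 100))
  # appended spectra are genuine copies from region 2
  pool <- cube$intensities[cube$region_labels == 2L, , drop = FALSE]
  for (i in (n0 + 1):(n0 + 5))
    expect_true(any(apply(pool, 1, identical, y = out$intensities[i, ])))
  expect_identical(make_disparate(cube, 2L, 0L), cube)
  expect_identical(make_disparate(cube, 2L, 100L, seed = 5L)$intensities,
                   out$intensities)
  expect_error(make_disparate(cube, 99L, 10L), "empty")
})

test_that("concatenation stacks masks and keeps regions distinct", {
  a <- small_cube()
  b <- homogenize(a, 0.9)
  out <- concatenate_cubes(a, b)
  expect_identical(n_pixels(out), 2L * n_pixels(a))
  expect_identical(out$mask_shape[2], 2L * a$mask_shape[2])
  expect_identical(max(out$region_labels), 2L * max(a$region_labels))
  pairs <- attr(out, "region_pairs")
  expect_identical(pairs[, "offset"], pairs[, "original"] + max(a$region_labels))

  shifted <- msi_cube(a$intensities, a$mz + 1, a$coords, a$mask_shape,
                      a$region_labels)
  expect_error(concatenate_cubes(a, shifted), "m/z axes")
})
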