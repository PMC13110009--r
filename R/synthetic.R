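#' Specification of a synthetic MALDI datacube
#'
#' Describes the statistical structure of a simulated MALDI-MSI experiment:
#' a tissue mask partitioned into regions, a panel of metabolite-like species
#' observed as [M+H]+/[M+Na]+/[M+K]+ adducts with short geometric isotope
#' envelopes, per-region characteristic intensity ratios, a set of shared
#' matrix-background peaks (mimicking CHCA matrix signal present everywhere),
#' and a multiplicative normally distributed intensity fluctuation.
#'
#' @param grid `c(width, height)` of the pixel grid.
#' @param n_regions Number of tissue regions k.
#' @param species_per_region Species characteristic of each region; total
#'   species = `n_regions * species_per_region`.
#' @param n_matrix_peaks Matrix-background peaks shared by all regions.
#' @param adduct_offsets m/z offsets (Th) added to each species monoisotopic
#'   mass; defaults are protonated, sodiated and potassiated adducts.
#' @param adduct_weights Relative abundance of each adduct.
#' @param isotope_peaks Isotope peaks per adduct (A, A+1, ...).
#' @param isotope_decay Geometric decay factor between successive isotopes.
#' @param region_intensity_ratios Optional k x n_species matrix of base
#'   intensities; drawn automatically when `NULL` (each region's own species
#'   high, all others low).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   intensity fluctuation (intensity = ratio * max(0, 1 + eps),
#'   eps ~ N(0, noise_cv)).
#' @param seed Integer seed; all generation is bit-reproducible given it.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid = c(152L, 307L), n_regions = 8L,
                           species_per_region = 3L, n_matrix_peaks = 6L,
                           adduct_offsets = c(1.00728, 22.98922, 38.96316),
                           adduct_weights = c(1, 0.5, 0.25),
                           isotope_peaks = 2L, isotope_decay = 0.4,
                           region_intensity_ratios = NULL,
                           noise_cv = 0.1, seed = 1L) {
  stopifnot(n_regions >= 1L, species_per_region >= 1L, n_matrix_peaks >= 0L,
            isotope_peaks >= 1L, noise_cv >= 0, isotope_decay > 0,
            length(adduct_offsets) == length(adduct_weights))
  if (anyDuplicated(adduct_offsets)) stop("adduct offsets must be distinct")
  if (!is.null(region_intensity_ratios)) {
    region_intensity_ratios <- as.matrix(region_intensity_ratios)
    if (nrow(region_intensity_ratios) != n_regions ||
        ncol(region_intensity_ratios) != n_regions * species_per_region)
      stop("region_intensity_ratios must be k x (k * species_per_region)")
    if (any(region_intensity_ratios < 0)) stop("intensity ratios must be >= 0")
  }
  structure(
    list(grid = as.integer(grid), n_regions = as.integer(n_regions),
         species_per_region = as.integer(species_per_region),
         n_matrix_peaks = as.integer(n_matrix_peaks),
         adduct_offsets = adduct_offsets, adduct_weights = adduct_weights,
         isotope_peaks = as.integer(isotope_peaks),
         isotope_decay = isotope_decay,
         region_intensity_ratios = region_intensity_ratios,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param path YAML file path.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname synthetic_spec
#' @param spec A `synthetic_spec` (write) — or for `read_spec_yaml`, the YAML
#'   file written by `write_spec_yaml`.
#' @export
read_spec_yaml <- function(path) {
  do.call(synthetic_spec, yaml::read_yaml(path))
}

#' Procedural tissue region mask
#'
#' Builds a labelled mask on a `width x height` grid: the foreground is an
#' ellipse inscribed in the grid (a stand-in for a tissue section outline) and
#' is partitioned into `n_regions` contiguous regions by a seeded Voronoi
#' tessellation (region = nearest of k randomly placed seed cells). Every
#' region is non-empty by construction (it contains its seed cell).
#'
#' @param grid `c(width, height)`.
#' @param n_regions Number of regions k (at most the foreground cell count).
#' @param seed Integer seed; the mask is deterministic given it.
#' @return Integer matrix with `height` rows and `width` columns; 0 =
#'   background, 1..k = region labels.
#' @export
generate_region_mask <- function(grid, n_regions, seed = 1L) {
  w <- as.integer(grid[1]); h <- as.integer(grid[2])
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be >= 1")
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  fg <- outer(seq_len(h), seq_len(w), function(y, x)
    ((x - cx) / (w / 2))^2 + ((y - cy) / (h / 2))^2 <= 1)
  cells <- which(fg, arr.ind = TRUE) # (row = y, col = x)
  if (n_regions > nrow(cells))
    stop("n_regions (", n_regions, ") exceeds foreground cell count (",
         nrow(cells), ")")
  lab <- withr::with_seed(seed, {
    seeds <- cells[sample.int(nrow(cells), n_regions), , drop = FALSE]
    d2 <- outer(cells[, 1], seeds[, 1], "-")^2 +
          outer(cells[, 2], seeds[, 2], "-")^2
    max.col(-d2, ties.method = "first")
  })
  mask <- matrix(0L, h, w)
  mask[cells] <- lab
  mask
}

# Deterministic m/z axis + per-region channel templates for a spec.
# Species masses are drawn uniformly in 100-1000 Th; channels are all
# species x adduct x isotope combinations plus matrix peaks, sorted by m/z.
spec_templates <- function(spec) {
  k <- spec$n_regions
  n_species <- k * spec$species_per_region
  n_ad <- length(spec$adduct_offsets)
  iso <- spec$isotope_peaks
  n_chan <- n_species * n_ad * iso + spec$n_matrix_peaks

  withr::with_seed(spec$seed + 1000L, {
    masses <- stats::runif(n_species, 100, 1000)
    matrix_mz <- if (spec$n_matrix_peaks > 0)
      stats::runif(spec$n_matrix_peaks, 100, 1000) else numeric(0)
    ratios <- spec$region_intensity_ratios
    if (is.null(ratios)) {
      ratios <- matrix(stats::runif(k * n_species, 0.05, 0.5), k, n_species)
      for (r in seq_len(k)) {
        own <- ((r - 1) * spec$species_per_region + 1):(r * spec$species_per_region)
        ratios[r, own] <- stats::runif(spec$species_per_region, 5, 10)
      }
    }
    matrix_base <- if (spec$n_matrix_peaks > 0)
      stats::runif(spec$n_matrix_peaks, 1, 5) else numeric(0)

    # channel m/z values: species block then matrix block, then sort
    neutron <- 1.00336
    mz <- numeric(n_chan)
    weight <- numeric(n_chan)     # per-channel multiplier on the species ratio
    species_of <- integer(n_chan) # 0 = matrix peak
    idx <- 1L
    for (j in seq_len(n_species)) for (a in seq_len(n_ad)) for (i in seq_len(iso)) {
      mz[idx] <- masses[j] + spec$adduct_offsets[a] + neutron * (i - 1)
      weight[idx] <- spec$adduct_weights[a] * spec$isotope_decay^(i - 1)
      species_of[idx] <- j
      idx <- idx + 1L
    }
    if (spec$n_matrix_peaks > 0) {
      rng <- idx:(idx + spec$n_matrix_peaks - 1L)
      mz[rng] <- matrix_mz
      weight[rng] <- matrix_base
      species_of[rng] <- 0L
    }
    while (anyDuplicated(mz)) mz[duplicated(mz)] <- mz[duplicated(mz)] + 1e-6
    ord <- order(mz)
    mz <- mz[ord]; weight <- weight[ord]; species_of <- species_of[ord]

    templates <- matrix(0, k, n_chan)
    for (c in seq_len(n_chan)) {
      templates[, c] <- if (species_of[c] == 0L) weight[c]
                        else ratios[, species_of[c]] * weight[c]
    }
    list(mz = mz, templates = templates)
  })
}

#' Synthesize an MSI datacube from a spec and region mask
#'
#' Every foreground mask cell becomes one pixel (canonical row-major (y, x)
#' order). A pixel in region r gets, in channel c, the region template value
#' times `max(0, 1 + eps)` with `eps ~ N(0, noise_cv)` — i.e. normally
#' distributed multiplicative fluctuation truncated at zero intensity. Matrix
#' background channels share one template row across all regions, so regions
#' differ only through their species ratios.
#'
#' @param spec A `synthetic_spec`.
#' @param mask Optional labelled mask matrix (as from
#'   [generate_region_mask()]); generated from the spec when `NULL`.
#' @return A labelled `msi_cube`.
#' @export
synthesize_cube <- function(spec, mask = NULL) {
  if (is.null(mask))
    mask <- generate_region_mask(spec$grid, spec$n_regions, spec$seed)
  if (!any(mask > 0L)) stop("mask has no foreground cells")
  if (max(mask) > spec$n_regions)
    stop("mask labels exceed spec n_regions")
  tpl <- spec_templates(spec)

  h <- nrow(mask); w <- ncol(mask)
  fg <- which(t(mask) > 0L)          # row-major (y, x) order over transposed mask
  x <- ((fg - 1L) %% w) + 1L
  y <- ((fg - 1L) %/% w) + 1L
  lab <- mask[cbind(y, x)]
  n <- length(fg); n_chan <- length(tpl$mz)

  X <- tpl$templates[lab, , drop = FALSE]
  if (spec$noise_cv > 0) {
    eps <- withr::with_seed(spec$seed + 2000L,
      matrix(stats::rnorm(n * n_chan, 0, spec$noise_cv), n, n_chan))
    X <- X * pmax(0, 1 + eps)
  }
  msi_cube(X, tpl$mz, cbind(x = x, y = y), c(w, h), lab)
}

#' Homogenization transform
#'
#' Blends every pixel towards the global mean spectrum: each pixel p_i in
#' region r is replaced by `p_i - s * mu_r + s * mu_w`, where mu_r and mu_w
#' are the region and whole-dataset mean spectra of the *input* cube. At
#' `s = 0` this is the identity; at `s = 0.9` each pixel carries 90% global
#' mean and 10% region mean around its own deviation, producing a dataset
#' whose clusters are much less distinct. The transform is linear, so the
#' post-transform mean of region r is exactly `(1-s) * mu_r + s * mu_w`.
#'
#' The formula can produce negative intensities; they are kept by default
#' (set `clip = TRUE` to truncate at zero, which breaks the exact mean
#' identity).
#'
#' @param cube A labelled `msi_cube`.
#' @param s Blending fraction in `[0, 1]`.
#' @param clip Truncate negative intensities at zero (default `FALSE`).
#' @return The transformed `msi_cube` (labels preserved).
#' @export
homogenize <- function(cube, s, clip = FALSE) {
  if (is.null(cube$region_labels)) stop("homogenize requires region labels")
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1)
    stop("s must be a single fraction in [0, 1]")
  ms <- region_mean_spectra(cube)
  lab <- cube$region_labels
  X <- cube$intensities
  fg <- lab > 0L
  mu_r <- ms$region[match(lab[fg], as.integer(rownames(ms$region))), , drop = FALSE]
  X[fg, ] <- X[fg, , drop = FALSE] - s * mu_r +
    s * matrix(ms$global, sum(fg), ncol(X), byrow = TRUE)
  if (clip) X[X < 0] <- 0
  msi_cube(X, cube$mz, cube$coords, cube$mask_shape, lab)
}

#' Disparate-cluster bootstrap
#'
#' Grows one region by sampling spectra from it with replacement and
#' appending the duplicates as new pixels, emulating datasets in which one
#' tissue class vastly outnumbers the rest (e.g. healthy tissue around a
#' small lesion). The original pixels are preserved bit-exactly as a prefix;
#' appended pixels take fresh coordinates on rows added below the original
#' mask and inherit the bootstrapped region's label.
#'
#' @param cube A labelled `msi_cube`.
#' @param region_id Label of the region to bootstrap from.
#' @param n_bootstrap Number of spectra to append (>= 0).
#' @param seed Integer seed for the resampling.
#' @return An `msi_cube` with `n_pixels(cube) + n_bootstrap` pixels.
#' @export
make_disparate <- function(cube, region_id, n_bootstrap, seed = 1L) {
  if (is.null(cube$region_labels)) stop("make_disparate requires region labels")
  n_bootstrap <- as.integer(n_bootstrap)
  if (n_bootstrap < 0L) stop("n_bootstrap must be >= 0")
  if (n_bootstrap == 0L) return(cube)
  pool <- which(cube$region_labels == region_id)
  if (length(pool) == 0L) stop("region ", region_id, " is empty")

  picks <- withr::with_seed(seed,
    pool[sample.int(length(pool), n_bootstrap, replace = TRUE)])

  w <- cube$mask_shape[1]; h0 <- cube$mask_shape[2]
  extra_rows <- ceiling(n_bootstrap / w)
  off <- seq_len(n_bootstrap) - 1L
  new_coords <- cbind(x = (off %% w) + 1L, y = h0 + (off %/% w) + 1L)

  msi_cube(rbind(cube$intensities, cube$intensities[picks, , drop = FALSE]),
           cube$mz,
           rbind(cube$coords, new_coords),
           c(w, h0 + extra_rows),
           c(cube$region_labels, rep(as.integer(region_id), n_bootstrap)))
}

#' Concatenate two datacubes (stacked masks)
#'
#' Joins two cubes that share an m/z axis into one dataset: pixels of `a`
#' followed by pixels of `b`, with `b`'s mask placed below `a`'s (y offset =
#' height of `a`). `b`'s region labels are offset by the largest label of `a`
#' so regions stay distinct; the pairing between original and offset labels
#' is recorded in the `region_pairs` attribute.
#'
#' @param a,b Labelled or unlabelled `msi_cube`s with identical m/z axes.
#' @return The combined `msi_cube`.
#' @export
concatenate_cubes <- function(a, b) {
  if (!identical(length(a$mz), length(b$mz)) || !isTRUE(all.equal(a$mz, b$mz)))
    stop("cubes have different m/z axes; re-bin before concatenating")
  off_y <- a$mask_shape[2]
  b_coords <- b$coords
  b_coords[, "y"] <- b_coords[, "y"] + off_y
  lab <- NULL
  pairs <- NULL
  if (!is.null(a$region_labels) && !is.null(b$region_labels)) {
    off_lab <- max(a$region_labels)
    b_lab <- ifelse(b$region_labels > 0L, b$region_labels + off_lab, 0L)
    lab <- c(a$region_labels, b_lab)
    ids <- sort(setdiff(unique(b$region_labels), 0L))
    pairs <- cbind(original = ids, offset = ids + off_lab)
  }
  out <- msi_cube(rbind(a$intensities, b$intensities), a$mz,
                  rbind(a$coords, b_coords),
                  c(max(a$mask_shape[1], b$mask_shape[1]),
                    off_y + b$mask_shape[2]),
                  lab)
  attr(out, "region_pairs") <- pairs
  out
}
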