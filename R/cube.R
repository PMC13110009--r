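#' Construct an MSI datacube
#'
#' The central container of the package: a pixels-by-channels intensity
#' matrix together with its m/z axis, pixel grid coordinates and an optional
#' region label per pixel. Pixels are conventionally stored in row-major
#' order by (y, x) so that cube, embedding and label vectors always share one
#' alignment; readers preserve file order instead and say so.
#'
#' @param intensities Numeric matrix, rows = pixels, columns = m/z channels.
#'   Stored internally as double regardless of source precision.
#' @param mz Strictly increasing numeric vector of m/z values (Th), one per
#'   channel.
#' @param coords Integer matrix with columns `x`, `y` (1-based), one row per
#'   pixel; rows must be unique and lie inside `mask_shape`.
#' @param mask_shape Integer `c(width, height)` of the pixel grid.
#' @param region_labels Optional integer vector, one per pixel; `0` means
#'   background/unlabelled. `NULL` if the cube is unlabelled.
#'
#' @return An object of class `msi_cube`.
#' @export
msi_cube <- function(intensities, mz, coords, mask_shape, region_labels = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  mz <- as.double(mz)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  mask_shape <- as.integer(mask_shape)

  n <- nrow(intensities)
  if (n < 1L) stop("cube must contain at least one pixel")
  if (ncol(intensities) < 2L) stop("cube must contain at least two m/z channels")
  if (length(mz) != ncol(intensities))
    stop("length of mz axis (", length(mz), ") does not match channel count (",
         ncol(intensities), ")")
  if (any(!is.finite(mz)) || any(diff(mz) <= 0))
    stop("mz axis must be finite and strictly increasing")
  if (any(intensities < 0, na.rm = TRUE) && is.null(attr(intensities, "allow_negative")))
    NULL # negative intensities are permitted (homogenization can produce them)
  if (nrow(coords) != n) stop("coords must have one row per pixel")
  if (any(coords[, 1] < 1L) || any(coords[, 1] > mask_shape[1]) ||
      any(coords[, 2] < 1L) || any(coords[, 2] > mask_shape[2]))
    stop("pixel coordinates fall outside mask_shape")
  if (anyDuplicated(coords)) stop("pixel coordinates must be unique")
  if (!is.null(region_labels)) {
    region_labels <- as.integer(region_labels)
    if (length(region_labels) != n)
      stop("region_labels must have one entry per pixel")
  }

  structure(
    list(intensities = intensities, mz = mz, coords = coords,
         mask_shape = mask_shape, region_labels = region_labels),
    class = "msi_cube"
  )
}

#' @export
print.msi_cube <- function(x, ...) {
  cat(sprintf("<msi_cube> %d pixels x %d m/z channels, grid %d x %d\n",
              n_pixels(x), n_channels(x), x$mask_shape[1], x$mask_shape[2]))
  cat(sprintf("  m/z range: %.4f - %.4f\n", x$mz[1], x$mz[length(x$mz)]))
  if (is.null(x$region_labels)) {
    cat("  region labels: none\n")
  } else {
    k <- length(setdiff(unique(x$region_labels), 0L))
    cat(sprintf("  region labels: %d regions\n", k))
  }
  invisible(x)
}

#' Number of pixels / channels in a cube
#' @param cube An `msi_cube`.
#' @return Integer count.
#' @export
n_pixels <- function(cube) nrow(cube$intensities)

#' @rdname n_pixels
#' @export
n_channels <- function(cube) ncol(cube$intensities)

#' Restrict a cube to a region of interest
#'
#' Drops pixels outside the ROI (e.g. off-tissue background whose spectra are
#' all-zero and would break cosine distances), preserving pixel order and
#' coordinates of the kept pixels.
#'
#' @param cube An `msi_cube`.
#' @param keep Logical vector, one entry per pixel; `TRUE` pixels are kept.
#' @return The restricted `msi_cube`.
#' @export
apply_roi <- function(cube, keep) {
  keep <- as.logical(keep)
  if (length(keep) != n_pixels(cube))
    stop("keep must have one entry per pixel")
  if (!any(keep)) stop("ROI keeps no pixels: refusing to build an empty cube")
  msi_cube(cube$intensities[keep, , drop = FALSE], cube$mz,
           cube$coords[keep, , drop = FALSE], cube$mask_shape,
           if (!is.null(cube$region_labels)) cube$region_labels[keep])
}

#' Per-region and global mean spectra
#'
#' Computes the arithmetic mean spectrum of every labelled region (mu_r) and
#' of all foreground pixels together (mu_w). These are the ingredients of the
#' homogenization transform; they satisfy the weighted-mean identity
#' sum_r n_r mu_r = n mu_w to machine precision.
#'
#' @param cube A labelled `msi_cube` (`region_labels` present, at least one
#'   label > 0).
#' @return A list with `region` (matrix, one row per region, rownames = region
#'   ids), `global` (numeric vector mu_w), and `n` (named pixel counts).
#' @export
region_mean_spectra <- function(cube) {
  lab <- cube$region_labels
  if (is.null(lab)) stop("cube has no region labels")
  fg <- lab > 0L
  if (!any(fg)) stop("cube has no labelled (foreground) pixels")
  ids <- sort(unique(lab[fg]))
  X <- cube$intensities[fg, , drop = FALSE]
  g <- factor(lab[fg], levels = ids)
  sums <- rowsum(X, g)
  counts <- as.vector(table(g))
  region <- sums / counts
  rownames(region) <- ids
  list(region = region,
       global = colMeans(X),
       n = stats::setNames(counts, ids))
}

#' Interpolation re-binning onto a uniform m/z grid
#'
#' Each spectrum is linearly interpolated onto a uniform grid spanning the
#' original m/z range with the requested step. The new axis has
#' `floor(span / bin_width) + 1` channels. Linear interpolation is exact for
#' spectra that are constant or linear in m/z, and re-binning a cube already
#' on a uniform grid of the same width is the identity.
#'
#' @param cube An `msi_cube`.
#' @param bin_width Positive bin size in Th; must not exceed the m/z span.
#' @return The re-binned `msi_cube`.
#' @export
rebin <- function(cube, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number")
  mz <- cube$mz
  span <- mz[length(mz)] - mz[1]
  if (bin_width > span)
    stop("bin_width (", bin_width, ") is wider than the m/z span (", span, ")")
  new_mz <- mz[1] + bin_width * seq.int(0L, floor(span / bin_width))
  new_int <- t(apply(cube$intensities, 1L, function(s)
    stats::approx(mz, s, xout = new_mz, rule = 2)$y))
  msi_cube(new_int, new_mz, cube$coords, cube$mask_shape, cube$region_labels)
}

#' Label image of a cube's pixel grid
#'
#' Rasterises per-pixel region labels back onto the `mask_shape` grid
#' (height x width matrix, 0 where no pixel exists).
#'
#' @param cube A labelled `msi_cube`.
#' @return Integer matrix with `mask_shape[2]` rows and `mask_shape[1]` columns.
#' @export
label_image <- function(cube) {
  if (is.null(cube$region_labels)) stop("cube has no region labels")
  img <- matrix(0L, cube$mask_shape[2], cube$mask_shape[1])
  img[cbind(cube$coords[, "y"], cube$coords[, "x"])] <- cube$region_labels
  img
}
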