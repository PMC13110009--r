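#' Rendering configuration for embedding images
#'
#' @param clip_percentiles `c(low, high)` percentile clip applied per
#'   embedding dimension before min-max scaling; the default (1, 99) stops a
#'   single anomalously embedded pixel from crushing the dynamic range of
#'   the whole image.
#' @param background RGB triple in `[0, 1]` for grid cells with no pixel.
#' @return An object of class `render_config`.
#' @export
render_config <- function(clip_percentiles = c(1, 99),
                          background = c(0, 0, 0)) {
  lo <- clip_percentiles[1]; hi <- clip_percentiles[2]
  if (!(lo >= 0 && lo < hi && hi <= 100))
    stop("clip_percentiles must satisfy 0 <= low < high <= 100")
  structure(list(clip_percentiles = clip_percentiles, background = background),
            class = "render_config")
}

#' Render a 3-D embedding as a spatial RGB image
#'
#' Each embedding dimension is clipped at its configured percentiles,
#' min-max scaled to `[0, 1]` and assigned to the R, G, B channel
#' (dim1 -> R, dim2 -> G, dim3 -> B, fixed); pixels are placed at their grid
#' coordinates. A dimension with zero range after clipping renders as 0.5.
#' The result is invariant (up to clipping effects) under per-dimension
#' affine rescaling of the embedding.
#'
#' @param embedding A 3-dimensional `msi_embedding`.
#' @param cube The source `msi_cube` (grid coordinates and shape).
#' @param cfg A [render_config()].
#' @return Numeric array `height x width x 3` with values in `[0, 1]`
#'   (writable with [png::writePNG()]).
#' @export
embedding_to_rgb <- function(embedding, cube, cfg = render_config()) {
  co <- if (inherits(embedding, "msi_embedding")) embedding$coordinates
        else as.matrix(embedding)
  if (ncol(co) != 3L)
    stop("RGB rendering requires a 3-dimensional embedding, got ", ncol(co))
  if (nrow(co) != n_pixels(cube))
    stop("embedding and cube pixel counts differ")
  probs <- cfg$clip_percentiles / 100
  scaled <- apply(co, 2L, function(v) {
    q <- stats::quantile(v, probs = probs, names = FALSE)
    v <- pmin(pmax(v, q[1]), q[2])
    rng <- q[2] - q[1]
    if (rng == 0) rep(0.5, length(v)) else (v - q[1]) / rng
  })
  w <- cube$mask_shape[1]; h <- cube$mask_shape[2]
  img <- array(rep(cfg$background, each = h * w), dim = c(h, w, 3L))
  at <- cbind(cube$coords[, "y"], cube$coords[, "x"])
  for (ch in 1:3) img[cbind(at, ch)] <- scaled[, ch]
  img
}

#' Heatmap of a hyperparameter grid's metric scores
#'
#' Tiles one metric of a [grid_search()] table over the perplexity /
#' exaggeration grid. Axes are discrete in grid order, so the usual
#' geometric grids read as log-scaled; missing (failed) cells render in a
#' distinct fill.
#'
#' @param table A [grid_search()] result (columns `perplexity`,
#'   `exaggeration` and the metric).
#' @param metric Column to plot.
#' @return A ggplot object.
#' @export
plot_metric_grid <- function(table, metric = "dci") {
  if (is.null(table) || nrow(table) == 0L) stop("empty score table")
  if (!metric %in% colnames(table)) stop("no column '", metric, "' in table")
  df <- as.data.frame(table)
  df$perplexity <- factor(df$perplexity, levels = sort(unique(df$perplexity)))
  df$exaggeration <- factor(df$exaggeration,
                            levels = sort(unique(df$exaggeration)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$perplexity,
                                   y = .data$exaggeration,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(na.value = "grey75") +
    ggplot2::labs(x = "perplexity", y = "exaggeration", fill = metric) +
    ggplot2::theme_minimal()
}
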