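#' Low-dimensional embedding of a datacube
#'
#' @param coordinates Numeric matrix, one row per pixel (cube order), one
#'   column per embedding dimension.
#' @param params List recording the generating algorithm and hyperparameters.
#' @return An object of class `msi_embedding`.
#' @export
msi_embedding <- function(coordinates, params = list()) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (any(!is.finite(coordinates)))
    stop("embedding contains non-finite coordinates")
  structure(list(coordinates = coordinates, params = params),
            class = "msi_embedding")
}

#' @export
print.msi_embedding <- function(x, ...) {
  cat(sprintf("<msi_embedding> %d pixels x %d dims (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$params$algorithm %||% "unknown algorithm"))
  invisible(x)
}

#' t-SNE hyperparameters
#'
#' The fixed configuration used throughout: 3 output components, cosine
#' metric, random initialisation, automatic learning rate (max(200, n /
#' exaggeration)), with perplexity and exaggeration as the two swept
#' hyperparameters. "Exaggeration" is the early-exaggeration factor — the
#' multiplier applied to input affinities during the early optimisation
#' phase (standard t-SNE implementations expose exaggeration only for that
#' phase).
#'
#' @param perplexity Positive perplexity; must satisfy `3 * perplexity <=
#'   n_pixels - 1` (the Barnes-Hut neighbourhood requirement).
#' @param exaggeration Early-exaggeration factor, >= 1.
#' @param n_components Output dimensionality (3 for RGB rendering).
#' @param metric `"cosine"` (rows L2-normalised, then Euclidean Barnes-Hut —
#'   equivalent affinities, since on the unit sphere squared Euclidean
#'   distance is twice the cosine distance) or `"euclidean"`.
#' @param init `"random"` (default) or `"pca"`.
#' @param seed Integer seed; embeddings are reproducible given it.
#' @param max_iter Gradient iterations.
#' @param theta Barnes-Hut accuracy trade-off (0 = exact).
#' @return An object of class `tsne_params`.
#' @export
tsne_params <- function(perplexity = 30, exaggeration = 12, n_components = 3L,
                        metric = c("cosine", "euclidean"),
                        init = c("random", "pca"), seed = 42L,
                        max_iter = 1000L, theta = 0.5) {
  stopifnot(perplexity >= 1, exaggeration >= 1, n_components >= 1L)
  structure(
    list(algorithm = "tsne", perplexity = perplexity,
         exaggeration = exaggeration, n_components = as.integer(n_components),
         metric = match.arg(metric), init = match.arg(init),
         seed = as.integer(seed), max_iter = as.integer(max_iter),
         theta = theta),
    class = "tsne_params")
}

#' UMAP hyperparameters
#'
#' Fixed configuration: 3 components, cosine metric, spectral initialisation;
#' `n_neighbours` is the swept hyperparameter.
#'
#' @param n_neighbours Neighbourhood size, >= 2 and < n_pixels.
#' @param n_components Output dimensionality.
#' @param metric Distance metric.
#' @param init Initialisation.
#' @param seed Integer seed.
#' @return An object of class `umap_params`.
#' @export
umap_params <- function(n_neighbours = 15L, n_components = 3L,
                        metric = "cosine", init = "spectral", seed = 42L) {
  stopifnot(n_neighbours >= 2L)
  structure(
    list(algorithm = "umap", n_neighbours = as.integer(n_neighbours),
         n_components = as.integer(n_components), metric = metric,
         init = init, seed = as.integer(seed)),
    class = "umap_params")
}

embedding_cache_get <- function(cache_dir, key) {
  if (is.null(cache_dir)) return(NULL)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

embedding_cache_put <- function(cache_dir, key, emb) {
  if (is.null(cache_dir)) return(invisible(NULL))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(emb, file.path(cache_dir, paste0(key, ".rds")))
  invisible(NULL)
}

prepare_spectra <- function(cube, metric) {
  X <- if (inherits(cube, "msi_cube")) cube$intensities else as.matrix(cube)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    zero <- which(nrm == 0)
    if (length(zero) > 0)
      stop("all-zero spectra at pixel(s) ",
           paste(utils::head(zero, 5), collapse = ", "),
           " — apply an ROI before embedding with the cosine metric")
    X <- X / nrm
  }
  X
}

#' Embed a datacube with t-SNE
#'
#' Runs Barnes-Hut t-SNE (via Rtsne) under the fixed configuration of
#' [tsne_params()]. Embeddings can be cached to disk keyed by the cube
#' content and parameters, which makes grid searches and optimizations
#' resumable.
#'
#' @param cube An `msi_cube` (or spectral matrix).
#' @param params A [tsne_params()].
#' @param cache_dir Optional directory for the embedding cache.
#' @return An `msi_embedding` with `params` recorded.
#' @export
run_tsne <- function(cube, params = tsne_params(), cache_dir = NULL) {
  X <- prepare_spectra(cube, params$metric)
  n <- nrow(X)
  if (3 * params$perplexity > n - 1)
    stop("perplexity ", params$perplexity, " too large for ", n,
         " pixels (need 3 * perplexity <= n - 1)")
  key <- rlang::hash(list("tsne", X, unclass(params)))
  cached <- embedding_cache_get(cache_dir, key)
  if (!is.null(cached)) return(cached)
  eta <- max(200, n / params$exaggeration) # sklearn-style "auto" learning rate
  fit <- withr::with_seed(params$seed,
    Rtsne::Rtsne(X, dims = params$n_components, perplexity = params$perplexity,
                 theta = params$theta, pca = identical(params$init, "pca"),
                 max_iter = params$max_iter, eta = eta,
                 exaggeration_factor = params$exaggeration,
                 check_duplicates = FALSE, num_threads = 1L))
  emb <- msi_embedding(fit$Y, unclass(params))
  embedding_cache_put(cache_dir, key, emb)
  emb
}

#' Embed a datacube with UMAP
#'
#' Runs UMAP (via uwot) with cosine metric and spectral initialisation;
#' single-threaded SGD so results are reproducible under the seed.
#'
#' @param cube An `msi_cube` (or spectral matrix).
#' @param params A [umap_params()].
#' @param cache_dir Optional directory for the embedding cache.
#' @return An `msi_embedding`.
#' @export
run_umap <- function(cube, params = umap_params(), cache_dir = NULL) {
  X <- if (inherits(cube, "msi_cube")) cube$intensities else as.matrix(cube)
  n <- nrow(X)
  if (params$n_neighbours >= n)
    stop("n_neighbours ", params$n_neighbours, " must be below the pixel count ", n)
  if (identical(params$metric, "cosine")) {
    zero <- which(sqrt(rowSums(X^2)) == 0)
    if (length(zero) > 0)
      stop("all-zero spectra at pixel(s) ",
           paste(utils::head(zero, 5), collapse = ", "),
           " — apply an ROI before embedding with the cosine metric")
  }
  key <- rlang::hash(list("umap", X, unclass(params)))
  cached <- embedding_cache_get(cache_dir, key)
  if (!is.null(cached)) return(cached)
  Y <- withr::with_seed(params$seed,
    uwot::umap(X, n_neighbors = params$n_neighbours,
               n_components = params$n_components, metric = params$metric,
               init = params$init, n_threads = 1L, n_sgd_threads = 0L))
  emb <- msi_embedding(Y, unclass(params))
  embedding_cache_put(cache_dir, key, emb)
  emb
}
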