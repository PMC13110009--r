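# Shared fixtures, memoized for the session. The "desk cube" is the scaled-
# down analogue of the study's 8-region synthetic MALDI dataset: ~2,000
# pixels, 150 m/z channels, 10% intensity CV. t-SNE test settings (300
# iterations, theta 0.8) trade a little embedding polish for speed; the
# hyperparameter trends are insensitive to this.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

test_cache_dir <- function() {
  d <- file.path(tempdir(), "dcims-test-cache")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

desk_spec <- function(noise_cv = 0.1, seed = 101L)
  synthetic_spec(grid = c(52L, 50L), n_regions = 8L, species_per_region = 3L,
                 n_matrix_peaks = 6L, isotope_peaks = 2L,
                 noise_cv = noise_cv, seed = seed)

desk_cube <- function() memo("desk_cube", synthesize_cube(desk_spec()))

# smaller labelled cube for fast embedder contract tests (~280 pixels)
small_cube <- function() memo("small_cube", synthesize_cube(
  synthetic_spec(grid = c(20L, 18L), n_regions = 4L, species_per_region = 2L,
                 n_matrix_peaks = 6L, isotope_peaks = 2L, noise_cv = 0.1,
                 seed = 7L)))

desk_tsne_params <- function(perplexity, exaggeration, seed = 1L)
  tsne_params(perplexity = perplexity, exaggeration = exaggeration,
              seed = seed, max_iter = 300L, theta = 0.8)

desk_tsne <- function(perplexity, exaggeration, seed = 1L) {
  memo(sprintf("tsne_%d_%d_%d", perplexity, exaggeration, seed),
       run_tsne(desk_cube(), desk_tsne_params(perplexity, exaggeration, seed),
                cache_dir = test_cache_dir()))
}

acceptance_grid <- function(seed) {
  memo(sprintf("grid_%d", seed),
       grid_search(desk_cube(), c(5L, 30L, 200L, 600L), c(1L, 12L, 100L),
                   tsne = desk_tsne_params(30, 12, seed = seed),
                   cache_dir = test_cache_dir()))
}

# median-aggregated grid over t-SNE seeds 1..3
acceptance_grid_median <- function() {
  memo("grid_median", {
    grids <- lapply(1:3, acceptance_grid)
    out <- grids[[1]][, c("perplexity", "exaggeration")]
    out$dci <- apply(sapply(grids, function(g) g$dci), 1, stats::median)
    out
  })
}
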