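#' Configuration for the comparator embedding-quality metrics
#'
#' @param knn_k Neighbour count for co-KNN accuracy.
#' @param triplets_per_point Random triplets sampled per anchor point.
#' @param triplet_seed Seed of the triplet sampling.
#' @param subsample Optional pixel index vector: all metrics restrict to this
#'   subset (share it with a DCI result's `sample_indices` for a fair
#'   comparison, and to bound the O(n^2) distance matrices on large cubes).
#' @param high_metric,low_metric Distances for the two spaces (cosine high /
#'   Euclidean low, the DCI conventions).
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(knn_k = 10L, triplets_per_point = 5L,
                          triplet_seed = 1L, subsample = NULL,
                          high_metric = c("cosine", "euclidean"),
                          low_metric = c("euclidean", "cosine")) {
  stopifnot(knn_k >= 1L, triplets_per_point >= 1L)
  structure(
    list(knn_k = as.integer(knn_k),
         triplets_per_point = as.integer(triplets_per_point),
         triplet_seed = as.integer(triplet_seed), subsample = subsample,
         high_metric = match.arg(high_metric),
         low_metric = match.arg(low_metric)),
    class = "metric_config")
}

as_points <- function(x) {
  if (inherits(x, "msi_cube")) x$intensities
  else if (inherits(x, "msi_embedding")) x$coordinates
  else as.matrix(x)
}

square_dist <- function(X, metric) as.matrix(condensed_pairwise(X, metric))

apply_subsample <- function(X, cfg) {
  if (is.null(cfg$subsample)) X else X[cfg$subsample, , drop = FALSE]
}

#' Co-k-nearest-neighbour accuracy
#'
#' Local structure preservation: the mean, over points, of the fraction of a
#' point's k nearest neighbours (self excluded) shared between the
#' high-dimensional and low-dimensional spaces. Distance ties are broken by
#' lowest index in both spaces.
#'
#' @param high,low Row-aligned point matrices (or cube / embedding objects).
#' @param cfg A [metric_config()].
#' @return Fraction in `[0, 1]`.
#' @export
knn_accuracy <- function(high, low, cfg = metric_config()) {
  H <- apply_subsample(as_points(high), cfg)
  L <- apply_subsample(as_points(low), cfg)
  n <- nrow(H); k <- cfg$knn_k
  if (n <= k) stop("need more than knn_k = ", k, " points, got ", n)
  Dh <- square_dist(H, cfg$high_metric); diag(Dh) <- Inf
  Dl <- square_dist(L, cfg$low_metric); diag(Dl) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nh <- order(Dh[i, ])[seq_len(k)] # stable radix order: ties -> lowest index
    nl <- order(Dl[i, ])[seq_len(k)]
    length(intersect(nh, nl)) / k
  }, numeric(1)))
}

triplet_score <- function(dh_ij, dh_il, dl_ij, dl_il) {
  sh <- sign(dh_ij - dh_il); sl <- sign(dl_ij - dl_il)
  if (sh == 0 || sl == 0) 0.5 else as.numeric(sh == sl)
}

#' Random-triplet accuracy
#'
#' Global structure preservation: for triplets (i, j, l), scores whether the
#' relative order of d(i,j) vs d(i,l) agrees between spaces (1 if the signs
#' agree, 0.5 if either comparison ties, 0 otherwise). By default
#' `triplets_per_point` triplets are sampled per anchor under the configured
#' seed; `exhaustive = TRUE` enumerates every anchored triplet instead.
#'
#' @inheritParams knn_accuracy
#' @param exhaustive Enumerate all triplets instead of sampling.
#' @return Fraction in `[0, 1]`.
#' @export
random_triplet_accuracy <- function(high, low, cfg = metric_config(),
                                    exhaustive = FALSE) {
  H <- apply_subsample(as_points(high), cfg)
  L <- apply_subsample(as_points(low), cfg)
  n <- nrow(H)
  if (n < 3L) stop("need at least 3 points, got ", n)
  Dh <- square_dist(H, cfg$high_metric)
  Dl <- square_dist(L, cfg$low_metric)
  if (exhaustive) {
    scores <- numeric(0)
    tot <- 0; s <- 0
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      prs <- utils::combn(others, 2L)
      for (c in seq_len(ncol(prs))) {
        j <- prs[1, c]; l <- prs[2, c]
        s <- s + triplet_score(Dh[i, j], Dh[i, l], Dl[i, j], Dl[i, l])
        tot <- tot + 1
      }
    }
    return(s / tot)
  }
  withr::with_seed(cfg$triplet_seed, {
    s <- 0; tot <- 0
    for (i in seq_len(n)) {
      for (t in seq_len(cfg$triplets_per_point)) {
        jl <- sample(setdiff(seq_len(n), i), 2L)
        s <- s + triplet_score(Dh[i, jl[1]], Dh[i, jl[2]],
                               Dl[i, jl[1]], Dl[i, jl[2]])
        tot <- tot + 1
      }
    }
    s / tot
  })
}

#' Spearman correlation of pairwise distances
#'
#' Global structure preservation: the Spearman rank correlation (average
#' ranks on ties) between the condensed pairwise distance vectors of the two
#' spaces. Invariant under any strictly increasing transform of either
#' vector. Inputs may be point matrices or precomputed `dist` objects.
#'
#' @inheritParams knn_accuracy
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_pairwise <- function(high, low, cfg = metric_config()) {
  dh <- if (inherits(high, "dist")) as.vector(high)
        else as.vector(condensed_pairwise(apply_subsample(as_points(high), cfg),
                                          cfg$high_metric))
  dl <- if (inherits(low, "dist")) as.vector(low)
        else as.vector(condensed_pairwise(apply_subsample(as_points(low), cfg),
                                          cfg$low_metric))
  if (length(dh) != length(dl)) stop("distance vectors differ in length")
  if (length(dh) < 3L) stop("need at least 3 pairs")
  if (stats::sd(dh) == 0 || stats::sd(dl) == 0)
    stop("undefined correlation: a distance vector is constant")
  stats::cor(dh, dl, method = "spearman")
}

#' Centroid-distance correlation (CDC)
#'
#' Labelled-data metric: per-class centroids (arithmetic means) are computed
#' in each space and the Spearman correlation between the two centroid
#' pairwise distance vectors is returned. Requires at least 3 classes (3
#' centroid pairs); with labels 0 / NA treated as unlabelled and excluded.
#'
#' @inheritParams knn_accuracy
#' @param labels Integer class label per point (0 / NA = unlabelled).
#' @return Correlation in `[-1, 1]`.
#' @export
centroid_distance_correlation <- function(high, low, labels,
                                          cfg = metric_config()) {
  H <- apply_subsample(as_points(high), cfg)
  L <- apply_subsample(as_points(low), cfg)
  if (!is.null(cfg$subsample)) labels <- labels[cfg$subsample]
  keep <- !is.na(labels) & labels > 0
  H <- H[keep, , drop = FALSE]; L <- L[keep, , drop = FALSE]
  g <- factor(labels[keep])
  if (nlevels(g) < 3L)
    stop("centroid-distance correlation needs at least 3 classes, got ",
         nlevels(g))
  ch <- rowsum(H, g) / as.vector(table(g))
  cl <- rowsum(L, g) / as.vector(table(g))
  dh <- as.vector(condensed_pairwise(ch, cfg$high_metric))
  dl <- as.vector(condensed_pairwise(cl, cfg$low_metric))
  if (stats::sd(dh) == 0 || stats::sd(dl) == 0)
    stop("undefined correlation: centroid distances are constant")
  stats::cor(dh, dl, method = "spearman")
}

#' Mean-based Dunn index
#'
#' Labelled-data metric on the embedding alone: the ratio of the mean
#' inter-class point-pair distance to the mean intra-class point-pair
#' distance (Euclidean). Values above 1 indicate class separation; a random
#' labelling of a symmetric cloud sits near 1.
#'
#' @param low Embedding point matrix (or `msi_embedding`).
#' @param labels Integer class label per point (0 / NA = unlabelled).
#' @param cfg A [metric_config()].
#' @return Ratio >= 0.
#' @export
mean_dunn_index <- function(low, labels, cfg = metric_config()) {
  L <- apply_subsample(as_points(low), cfg)
  if (!is.null(cfg$subsample)) labels <- labels[cfg$subsample]
  keep <- !is.na(labels) & labels > 0
  L <- L[keep, , drop = FALSE]
  g <- as.integer(factor(labels[keep]))
  ids <- sort(unique(g))
  if (length(ids) < 2L) stop("need at least 2 classes")
  sizes <- tabulate(g)
  if (any(sizes == 1L))
    stop("singleton class(es): ",
         paste(levels(factor(labels[keep]))[sizes == 1L], collapse = ", "),
         " — intra-class mean distance undefined")
  D <- as.matrix(stats::dist(L))
  same <- outer(g, g, "==")
  ut <- upper.tri(D)
  intra <- mean(D[ut & same])
  inter <- mean(D[ut & !same])
  if (intra == 0)
    stop("intra-class mean distance is zero (coincident points); ratio undefined")
  inter / intra
}

#' Evaluate all applicable comparator metrics on one embedding
#'
#' Convenience wrapper returning a one-row-per-metric tibble; the labelled
#' metrics (CDC, mean Dunn) are included only when labels are supplied.
#'
#' @inheritParams knn_accuracy
#' @param labels Optional class labels for the labelled metrics.
#' @return A tibble with columns `metric`, `value`.
#' @export
comparator_metrics <- function(high, low, cfg = metric_config(), labels = NULL) {
  out <- tibble::tibble(
    metric = c("knn_accuracy", "random_triplet_accuracy", "spearman_pairwise"),
    value = c(knn_accuracy(high, low, cfg),
              random_triplet_accuracy(high, low, cfg),
              spearman_pairwise(high, low, cfg)))
  if (!is.null(labels)) {
    out <- rbind(out, tibble::tibble(
      metric = c("centroid_distance_correlation", "mean_dunn_index"),
      value = c(centroid_distance_correlation(high, low, labels, cfg),
                mean_dunn_index(low, labels, cfg))))
  }
  out
}
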