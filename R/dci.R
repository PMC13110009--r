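#' Parameters of the DCI score
#'
#' @param sample_fraction Fraction of pixels used as representatives
#'   (k = round(n * fraction); the score is insensitive to this over roughly
#'   0.5--25%, and 1% keeps cost low).
#' @param high_metric Distance in the spectral (high-dimensional) space;
#'   cosine by default, matching the metric used for the embeddings
#'   themselves. A Euclidean override exists mainly so identity checks can
#'   use one metric in both spaces.
#' @param low_metric Distance in the embedding space (Euclidean).
#' @param linkage_method Agglomeration rule for both dendrograms (average
#'   linkage: stable cluster shapes, monotone heights).
#' @param kmeans_seed Seed of the representative-sampling k-means; recorded
#'   in the result for provenance.
#' @param min_samples Floor on the representative count.
#'
#' @return An object of class `dci_params`.
#' @export
dci_params <- function(sample_fraction = 0.01,
                       high_metric = c("cosine", "euclidean"),
                       low_metric = c("euclidean", "cosine"),
                       linkage_method = "average",
                       kmeans_seed = 1L, min_samples = 3L) {
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  structure(
    list(sample_fraction = sample_fraction,
         high_metric = match.arg(high_metric),
         low_metric = match.arg(low_metric),
         linkage_method = linkage_method,
         kmeans_seed = as.integer(kmeans_seed),
         min_samples = as.integer(min_samples)),
    class = "dci_params")
}

#' Condensed pairwise distances
#'
#' Computes the upper-triangle pairwise distance vector over the rows of a
#' matrix, in the standard condensed ordering (pairs (i, j), i < j,
#' lexicographic by i then j — the ordering of [stats::dist()]). Cosine
#' distance is `1 - u.v / (|u||v|)`, clamped at zero against floating-point
#' undershoot.
#'
#' @param points Numeric matrix (rows = points).
#' @param metric `"euclidean"` or `"cosine"`.
#' @return A `stats::dist` object (the package's condensed-vector type).
#' @export
condensed_pairwise <- function(points, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  if (any(!is.finite(points))) stop("points contain non-finite values")
  if (metric == "euclidean") return(stats::dist(points))
  nrm <- sqrt(rowSums(points^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0)
    stop("cosine distance undefined for all-zero row(s): ",
         paste(utils::head(zero, 5), collapse = ", "),
         " — consider ROI-filtering background pixels")
  sim <- tcrossprod(points / nrm)
  d <- 1 - sim
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA agglomeration of a condensed distance vector: at each step the two
#' clusters with the smallest mean inter-cluster distance merge, and the
#' recorded height is that mean. Average linkage is monotone, so merge
#' heights never decrease; this is asserted on every tree. Exact ties are
#' resolved by the agglomeration implementation's deterministic ordering.
#'
#' @param d A `stats::dist` object (or condensed numeric vector with a
#'   `Size` attribute).
#' @param method Linkage rule; average by default.
#' @return An object of class `linkage_tree` wrapping the merge sequence
#'   (`$merge`, `$height` as in [stats::hclust()]) and the leaf count `$n`.
#' @export
average_linkage <- function(d, method = "average") {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (any(!is.finite(d))) stop("distances contain non-finite values")
  h <- stats::hclust(d, method = method)
  if (any(diff(h$height) < -1e-10 * max(abs(h$height), 1)))
    stop("non-monotone linkage heights (method '", method, "')")
  structure(list(merge = h$merge, height = h$height, n = attr(d, "Size"),
                 hclust = h),
            class = "linkage_tree")
}

#' Cophenetic distances of a linkage tree
#'
#' For each pair of leaves, the height of the lowest merge that unites them —
#' the dendrogram's own notion of distance, summarising cluster relationships
#' at every granularity rather than single pointwise distances.
#'
#' @param tree A `linkage_tree`.
#' @return A `stats::dist` object of cophenetic distances.
#' @export
cophenetic_distances <- function(tree) {
  if (!inherits(tree, "linkage_tree")) stop("tree must be a linkage_tree")
  stats::cophenetic(tree$hclust)
}

#' Arithmetic-mean normalized mutual information of two value vectors
#'
#' Both vectors are converted to categorical labels by exact-value equality
#' (each distinct value is one category; no binning — merge heights are
#' replicated bit-exactly within a dendrogram, so cophenetic vectors are
#' natural categorical data) and NMI = I(A;B) / ((H(A) + H(B)) / 2) is
#' returned, with natural logarithms. Degenerate conventions: if both vectors
#' are constant the score is 1; if exactly one is constant it is 0 (a
#' constant summary carries no information about a varying one).
#'
#' @param a,b Equal-length numeric vectors or `dist` objects.
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b))
    stop("vectors have different lengths (", length(a), " vs ", length(b), ")")
  la <- match(a, unique(a))
  lb <- match(b, unique(b))
  tab <- table(la, lb)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- ent(pa); hb <- ent(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pij <- as.vector(p); pexp <- as.vector(outer(pa, pb))
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / pexp[nz]))
  min(1, max(0, mi / ((ha + hb) / 2)))
}

#' Representative pixel sampling by k-means
#'
#' Clusters the low-dimensional embedding into k = max(min_samples,
#' round(n * sample_fraction)) groups and returns, for each centroid, the
#' index of the nearest pixel (Euclidean; ties to the lowest index).
#' Duplicate representatives (two centroids claiming the same pixel) are
#' deduplicated, so fewer than k indices may be returned. k-means uses 10
#' random restarts under the recorded seed, making the sample deterministic.
#' If the embedding has fewer distinct rows than k (e.g. a degenerate
#' constant embedding), a seeded uniform sample of pixel indices is returned
#' instead.
#'
#' @param embedding An `msi_embedding` or coordinate matrix.
#' @param params A [dci_params()].
#' @return Sorted integer vector of pixel indices.
#' @export
sample_representatives <- function(embedding, params = dci_params()) {
  X <- if (inherits(embedding, "msi_embedding")) embedding$coordinates
       else as.matrix(embedding)
  if (any(!is.finite(X))) stop("embedding contains non-finite values")
  n <- nrow(X)
  if (n < params$min_samples)
    stop("need at least ", params$min_samples, " pixels, got ", n)
  k <- max(params$min_samples, round(n * params$sample_fraction))
  k <- min(k, n)
  if (k == n) return(seq_len(n))
  if (nrow(unique(X)) < k)
    return(sort(withr::with_seed(params$kmeans_seed, sample.int(n, k))))
  km <- withr::with_seed(params$kmeans_seed,
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 100))
  C <- km$centers
  d2 <- matrix(rowSums(X^2), n, k) - 2 * X %*% t(C) +
    matrix(rowSums(C^2), n, k, byrow = TRUE)
  sort(unique(apply(d2, 2L, which.min)))
}

#' Dimensional Cophenetic Integrity
#'
#' Scores how well a low-dimensional embedding preserves the hierarchical
#' cluster relationships of its high-dimensional datacube, in `[0, 1]`:
#'
#' 1. sample representative pixels by k-means in the embedding
#'    ([sample_representatives()]);
#' 2. compute condensed pairwise distances over the sampled pixels — cosine
#'    on the spectra, Euclidean on the embedding coordinates;
#' 3. cluster each space by average linkage and extract both cophenetic
#'    distance vectors;
#' 4. return the arithmetic-mean normalized mutual information between the
#'    two cophenetic vectors.
#'
#' A score of 1 means the embedding's dendrogram carries exactly the
#' information of the spectral dendrogram over the sampled pixels; scores
#' near 0 mean the cluster relationships were destroyed. Note the sampling
#' runs in the embedding, so different embeddings of one cube are scored on
#' (slightly) different representative sets — pass `indices` to pin the
#' sample, e.g. when comparing embeddings on a common subset.
#'
#' @param cube An `msi_cube` (or spectral matrix) — the high-dimensional
#'   space.
#' @param embedding An `msi_embedding` (or coordinate matrix), row-aligned
#'   with the cube.
#' @param params A [dci_params()].
#' @param indices Optional fixed representative indices (skips sampling).
#' @return An object of class `dci_result`: `$score`, `$sample_indices`,
#'   `$coph_high`, `$coph_low`, `$params`.
#' @export
dci <- function(cube, embedding, params = dci_params(), indices = NULL) {
  H <- if (inherits(cube, "msi_cube")) cube$intensities else as.matrix(cube)
  L <- if (inherits(embedding, "msi_embedding")) embedding$coordinates
       else as.matrix(embedding)
  if (nrow(H) != nrow(L))
    stop("cube (", nrow(H), " pixels) and embedding (", nrow(L),
         " rows) are not aligned")
  if (is.null(indices)) indices <- sample_representatives(L, params)
  dh <- condensed_pairwise(H[indices, , drop = FALSE], params$high_metric)
  dl <- condensed_pairwise(L[indices, , drop = FALSE], params$low_metric)
  ch <- cophenetic_distances(average_linkage(dh, params$linkage_method))
  cl <- cophenetic_distances(average_linkage(dl, params$linkage_method))
  structure(
    list(score = normalized_mutual_information(ch, cl),
         sample_indices = indices, coph_high = ch, coph_low = cl,
         params = params),
    class = "dci_result")
}

#' @export
print.dci_result <- function(x, ...) {
  cat(sprintf("<dci_result> score = %.4f over %d representative pixels\n",
              x$score, length(x$sample_indices)))
  invisible(x)
}

#' Serialize a DCI result as JSON
#'
#' Writes the score with full provenance: parameters, sampled pixel indices
#' and both condensed cophenetic vectors.
#'
#' @param result A `dci_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dci_json <- function(result, path) {
  jsonlite::write_json(
    list(score = result$score,
         sample_indices = result$sample_indices,
         params = unclass(result$params),
         coph_high = as.vector(result$coph_high),
         coph_low = as.vector(result$coph_low)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a condensed vector as a square CSV matrix
#'
#' Convenience for inspecting cophenetic structure (heat-map style): expands
#' a condensed `dist` into its full symmetric matrix and writes it as CSV.
#'
#' @param d A `stats::dist` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_condensed_csv <- function(d, path) {
  utils::write.csv(as.matrix(d), path, row.names = FALSE)
  invisible(path)
}
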