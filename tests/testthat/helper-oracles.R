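# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (stats::cophenetic, vectorised distance code): they are
# plain loops over definitions.

# Cophenetic distances by explicit dendrogram traversal: walk the merge
# sequence, tracking each cluster's leaf set; the first merge uniting i and j
# sets their cophenetic distance.
oracle_cophenetic <- function(tree) {
  n <- tree$n
  D <- matrix(NA_real_, n, n)
  members <- lapply(seq_len(n), identity)        # leaf sets, by leaf id
  node_members <- vector("list", n - 1L)         # by internal node id
  get_set <- function(code) if (code < 0) members[[-code]] else node_members[[code]]
  for (s in seq_len(n - 1L)) {
    A <- get_set(tree$merge[s, 1]); B <- get_set(tree$merge[s, 2])
    for (a in A) for (b in B) {
      D[a, b] <- tree$height[s]; D[b, a] <- tree$height[s]
    }
    node_members[[s]] <- c(A, B)
  }
  stats::as.dist(D)
}

oracle_euclidean <- function(u, v) sqrt(sum((u - v)^2))
oracle_cosine <- function(u, v)
  1 - sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))

oracle_dist_matrix <- function(X, metric) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  f <- if (metric == "cosine") oracle_cosine else oracle_euclidean
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    D[i, j] <- f(X[i, ], X[j, ])
  D
}

# co-KNN accuracy by definition: per point, intersect the k nearest neighbour
# sets (self excluded, ties by lowest index).
oracle_knn_accuracy <- function(H, L, k, high_metric, low_metric) {
  Dh <- oracle_dist_matrix(H, high_metric); diag(Dh) <- Inf
  Dl <- oracle_dist_matrix(L, low_metric); diag(Dl) <- Inf
  n <- nrow(H)
  acc <- 0
  for (i in seq_len(n)) {
    nh <- order(Dh[i, ])[seq_len(k)]
    nl <- order(Dl[i, ])[seq_len(k)]
    acc <- acc + length(intersect(nh, nl)) / k
  }
  acc / n
}

# random-triplet accuracy by full enumeration of anchored triplets.
oracle_triplet_accuracy <- function(H, L, high_metric, low_metric) {
  Dh <- oracle_dist_matrix(H, high_metric)
  Dl <- oracle_dist_matrix(L, low_metric)
  n <- nrow(H)
  s <- 0; tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) {
    if (j >= l || j == i || l == i) next
    sh <- sign(Dh[i, j] - Dh[i, l]); sl <- sign(Dl[i, j] - Dl[i, l])
    s <- s + if (sh == 0 || sl == 0) 0.5 else as.numeric(sh == sl)
    tot <- tot + 1
  }
  s / tot
}
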