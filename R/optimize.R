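#' Hyperparameter search space for DCI-guided optimization
#'
#' Integer box over t-SNE perplexity and exaggeration, with the budget of the
#' Gaussian-process optimization. Defaults mirror the study configuration:
#' perplexity 5--10000, exaggeration 1--1000, 120 calls of which 60 are
#' initial space-filling points, seed 42. The perplexity upper bound is
#' clipped to the cube's feasible range at run time.
#'
#' @param perplexity_range Integer `c(lo, hi)`.
#' @param exaggeration_range Integer `c(lo, hi)`.
#' @param n_calls Total objective evaluations.
#' @param n_initial_points Space-filling evaluations before the surrogate is
#'   used (<= n_calls).
#' @param seed Integer seed for the whole optimization.
#' @return An object of class `search_space`.
#' @export
search_space <- function(perplexity_range = c(5L, 10000L),
                         exaggeration_range = c(1L, 1000L),
                         n_calls = 120L, n_initial_points = 60L, seed = 42L) {
  stopifnot(perplexity_range[1] <= perplexity_range[2],
            exaggeration_range[1] <= exaggeration_range[2],
            n_initial_points <= n_calls, n_calls >= 1L)
  structure(
    list(perplexity_range = as.integer(perplexity_range),
         exaggeration_range = as.integer(exaggeration_range),
         n_calls = as.integer(n_calls),
         n_initial_points = as.integer(n_initial_points),
         seed = as.integer(seed)),
    class = "search_space")
}

#' Grid search of t-SNE hyperparameters scored by DCI
#'
#' Embeds the cube at every (perplexity, exaggeration) combination and scores
#' each embedding with [dci()]. A failing cell (e.g. an infeasible
#' perplexity) is recorded with `NA` score and the error message; it does not
#' abort the grid. With a `cache_dir`, embeddings are cached and the grid is
#' resumable.
#'
#' @param cube An `msi_cube`.
#' @param perplexities,exaggerations Integer vectors spanning the grid.
#' @param dci_params A [dci_params()].
#' @param tsne Base [tsne_params()] supplying seed / iterations / theta for
#'   every cell (its perplexity and exaggeration are overridden per cell).
#' @param cache_dir Optional embedding cache directory.
#' @param labels Optional region labels: when given, the labelled and
#'   unlabelled comparator metrics are evaluated per cell as extra columns.
#' @param metric_cfg A [metric_config()] for the comparators.
#' @return A tibble with one row per grid cell: `perplexity`, `exaggeration`,
#'   `dci`, `error`, and comparator columns when requested.
#' @export
grid_search <- function(cube, perplexities, exaggerations,
                        dci_params = dcims::dci_params(), tsne = tsne_params(),
                        cache_dir = NULL, labels = NULL, metric_cfg = NULL) {
  stopifnot(length(perplexities) > 0, length(exaggerations) > 0)
  cells <- expand.grid(perplexity = as.integer(perplexities),
                       exaggeration = as.integer(exaggerations))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$perplexity[i]; e <- cells$exaggeration[i]
    res <- tryCatch({
      tp <- tsne
      tp$perplexity <- p; tp$exaggeration <- e
      emb <- run_tsne(cube, tp, cache_dir = cache_dir)
      r <- dci(cube, emb, dci_params)
      row <- tibble::tibble(perplexity = p, exaggeration = e,
                            dci = r$score, error = NA_character_)
      if (!is.null(metric_cfg)) {
        cfg <- metric_cfg
        cfg$subsample <- r$sample_indices
        cm <- comparator_metrics(cube, emb, cfg, labels = labels)
        for (j in seq_len(nrow(cm))) row[[cm$metric[j]]] <- cm$value[j]
      }
      row
    }, error = function(err) {
      tibble::tibble(perplexity = p, exaggeration = e,
                     dci = NA_real_, error = conditionMessage(err))
    })
    res
  })
  do.call(rbind, rows)
}

# ---- Gaussian-process surrogate (Matern 5/2, expected improvement) --------

matern52 <- function(X1, X2, lengthscales) {
  r2 <- outer(rowSums(sweep(X1, 2, lengthscales, "/")^2), rep(1, nrow(X2))) -
    2 * (sweep(X1, 2, lengthscales, "/") %*% t(sweep(X2, 2, lengthscales, "/"))) +
    outer(rep(1, nrow(X1)), rowSums(sweep(X2, 2, lengthscales, "/")^2))
  a <- sqrt(5 * pmax(r2, 0))
  (1 + a + a^2 / 3) * exp(-a)
}

gp_fit <- function(X, y, nugget = 1e-6) {
  mu <- mean(y); sdy <- stats::sd(y)
  if (sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  best <- NULL
  for (l in c(0.05, 0.1, 0.2, 0.3, 0.5, 1.0)) {
    K <- matern52(X, X, rep(l, ncol(X))) + diag(nugget, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    loglik <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || loglik > best$loglik)
      best <- list(l = l, ch = ch, alpha = alpha, loglik = loglik)
  }
  if (is.null(best)) stop("GP fit failed: kernel matrix not factorizable")
  list(X = X, mu = mu, sdy = sdy, l = best$l, ch = best$ch, alpha = best$alpha)
}

gp_predict <- function(fit, Xnew) {
  Ks <- matern52(Xnew, fit$X, rep(fit$l, ncol(Xnew)))
  m <- as.vector(Ks %*% fit$alpha)
  v <- backsolve(fit$ch, t(Ks), transpose = TRUE)
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdy * m, sd = fit$sdy * sqrt(var))
}

expected_improvement <- function(pred, best_y) {
  # maximization EI
  z <- (pred$mean - best_y) / pred$sd
  (pred$mean - best_y) * stats::pnorm(z) + pred$sd * stats::dnorm(z)
}

#' Bayesian optimization of embedding hyperparameters with DCI objective
#'
#' Maximises DCI over the integer (perplexity, exaggeration) box using a
#' Gaussian-process surrogate (Matern 5/2 kernel, lengthscale chosen by
#' marginal likelihood) with expected-improvement acquisition. The first
#' `n_initial_points` evaluations are a seeded Latin-hypercube design; each
#' further point maximises EI over a large random candidate set of unvisited
#' integer points. Objective failures are recorded in the trace with `NA`
#' score (treated as the worst observed value by the surrogate) and excluded
#' from the reported best; if every point fails the optimization errors.
#'
#' For testing optimizer behaviour against an analytic optimum, pass
#' `objective` — a `function(perplexity, exaggeration)` returning a scalar to
#' maximise — in place of a cube.
#'
#' @param cube An `msi_cube` (ignored when `objective` is given).
#' @param space A [search_space()].
#' @param dci_params A [dci_params()].
#' @param tsne Base [tsne_params()] for the embeddings.
#' @param cache_dir Optional embedding cache directory.
#' @param objective Optional replacement objective `function(p, e)`.
#' @return An object of class `dci_opt_trace`: `$trace` (tibble of
#'   `iteration`, `perplexity`, `exaggeration`, `score`, `wall_time`),
#'   `$best_params`, `$best_score`.
#' @export
bayes_optimize <- function(cube = NULL, space = search_space(),
                           dci_params = dcims::dci_params(), tsne = tsne_params(),
                           cache_dir = NULL, objective = NULL) {
  pr <- space$perplexity_range
  er <- space$exaggeration_range
  if (is.null(objective)) {
    if (is.null(cube)) stop("either a cube or an objective is required")
    n <- n_pixels(cube)
    pr[2] <- min(pr[2], floor((n - 1) / 3)) # feasible perplexity for BH t-SNE
    if (pr[1] > pr[2]) stop("no feasible perplexity for a ", n, "-pixel cube")
    objective <- function(p, e) {
      tp <- tsne
      tp$perplexity <- p; tp$exaggeration <- e
      dci(cube, run_tsne(cube, tp, cache_dir = cache_dir), dci_params)$score
    }
  }

  rand_point <- function() c(sample(pr[1]:pr[2], 1L), sample(er[1]:er[2], 1L))
  init <- withr::with_seed(space$seed, {
    u <- lhs::randomLHS(space$n_initial_points, 2L)
    pts <- cbind(pr[1] + round(u[, 1] * (pr[2] - pr[1])),
                 er[1] + round(u[, 2] * (er[2] - er[1])))
    seen <- character(0)
    for (i in seq_len(nrow(pts))) {
      while (paste(pts[i, ], collapse = ",") %in% seen)
        pts[i, ] <- rand_point()
      seen <- c(seen, paste(pts[i, ], collapse = ","))
    }
    pts
  })

  evals <- matrix(NA_real_, 0L, 2L)
  scores <- numeric(0)
  times <- numeric(0)
  eval_point <- function(p, e) {
    t0 <- Sys.time()
    s <- tryCatch(objective(p, e), error = function(err) NA_real_)
    evals <<- rbind(evals, c(p, e))
    scores <<- c(scores, s)
    times <<- c(times, as.numeric(Sys.time() - t0, units = "secs"))
  }
  for (i in seq_len(nrow(init))) eval_point(init[i, 1], init[i, 2])

  scale01 <- function(P)
    cbind((P[, 1] - pr[1]) / max(1, pr[2] - pr[1]),
          (P[, 2] - er[1]) / max(1, er[2] - er[1]))

  n_rest <- space$n_calls - space$n_initial_points
  for (t in seq_len(n_rest)) {
    y <- scores
    if (all(is.na(y))) {
      if (nrow(evals) >= space$n_calls || t == n_rest)
        stop("objective failed at every evaluated point")
      pt <- withr::with_seed(space$seed + 7000L + t, rand_point())
      eval_point(pt[1], pt[2])
      next
    }
    y[is.na(y)] <- min(y, na.rm = TRUE) # failures pinned to the worst value
    nxt <- withr::with_seed(space$seed + 5000L + t, {
      cand <- cbind(sample(pr[1]:pr[2], 1000L, replace = TRUE),
                    sample(er[1]:er[2], 1000L, replace = TRUE))
      seen <- paste(evals[, 1], evals[, 2])
      cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% seen), , drop = FALSE]
      if (nrow(cand) == 0L) cand <- rbind(rand_point())
      fit <- tryCatch(gp_fit(scale01(evals), y), error = function(e) NULL)
      if (is.null(fit)) {
        cand[sample.int(nrow(cand), 1L), ]
      } else {
        ei <- expected_improvement(gp_predict(fit, scale01(cand)),
                                   max(y, na.rm = TRUE))
        cand[which.max(ei), ]
      }
    })
    eval_point(nxt[1], nxt[2])
  }

  if (all(is.na(scores))) stop("objective failed at every evaluated point")
  best <- which.max(ifelse(is.na(scores), -Inf, scores))
  structure(
    list(trace = tibble::tibble(iteration = seq_along(scores),
                                perplexity = evals[, 1],
                                exaggeration = evals[, 2],
                                score = scores, wall_time = times),
         best_params = list(perplexity = evals[best, 1],
                            exaggeration = evals[best, 2]),
         best_score = scores[best]),
    class = "dci_opt_trace")
}

#' @export
print.dci_opt_trace <- function(x, ...) {
  cat(sprintf(
    "<dci_opt_trace> %d evaluations; best score %.4f at perplexity %d, exaggeration %d\n",
    nrow(x$trace), x$best_score, x$best_params$perplexity,
    x$best_params$exaggeration))
  invisible(x)
}

#' Convergence plot of an optimization trace
#'
#' Per-iteration objective score with a moving average (window 5).
#'
#' @param trace A `dci_opt_trace`.
#' @param window Moving-average window.
#' @return A ggplot object.
#' @export
plot_convergence <- function(trace, window = 5L) {
  df <- trace$trace
  ma <- stats::filter(ifelse(is.na(df$score), min(df$score, na.rm = TRUE),
                             df$score),
                      rep(1 / window, window), sides = 1)
  df$moving_avg <- as.numeric(ma)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score), na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$moving_avg), colour = "firebrick",
                       na.rm = TRUE) +
    ggplot2::labs(x = "iteration", y = "DCI score",
                  title = "Optimization trace (points) and moving average (line)") +
    ggplot2::theme_minimal()
}

#' Serialize an optimization trace
#'
#' @param trace A `dci_opt_trace`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the trace.
#' @export
write_trace <- function(trace, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(
      list(best_params = trace$best_params, best_score = trace$best_score,
           trace = trace$trace),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path))
    utils::write.csv(trace$trace, csv_path, row.names = FALSE)
  invisible(trace)
}
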