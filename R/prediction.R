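#' Kernel configuration for the prediction model
#'
#' The initial probability vector of a query point is built from its `mu`
#' nearest neighbours in the point cloud, Gaussian-weighted with bandwidth
#' `sigma` on the normalized feature scale.
#'
#' @param mu neighbour count (default 14).
#' @param sigma kernel bandwidth (default 0.0378, normalized units).
#' @return A `kernel_config` object.
#' @export
kernel_config <- function(mu = 14, sigma = 0.0378) {
  if (mu < 1) abort("mu must be >= 1", "progmapper_config_error")
  if (sigma <= 0) abort("sigma must be positive", "progmapper_config_error")
  structure(list(mu = as.integer(mu), sigma = sigma), class = "kernel_config")
}

# mu nearest neighbours of x in cloud (rows), excluding `exclude`;
# ties at the cutoff distance break by point index (deterministic)
nearest_neighbours <- function(x, cloud, mu, exclude = NULL) {
  d2 <- colSums((t(cloud) - x)^2)
  if (!is.null(exclude)) d2[exclude] <- Inf
  ord <- order(d2, seq_along(d2))
  idx <- ord[seq_len(mu)]
  list(idx = idx, dist2 = d2[idx])
}

#' Kernel-weighted initial probability vector over mapper clusters
#'
#' Finds the `mu` nearest cloud points to the query, normalizes their
#' Gaussian kernel weights to sum to one, splits every neighbour's weight
#' equally among the clusters containing it (its multiplicity), zeroes the
#' entries of dead clusters (no outgoing arrows, hence useless for
#' prediction) and rescales the rest to a probability vector.
#'
#' @param x numeric query feature vector.
#' @param cloud numeric matrix: the point cloud (rows aligned with the
#'   graph's point indices).
#' @param graph a [build_mapper_graph()] result.
#' @param model a [build_transition_model()] result (supplies the live
#'   flags).
#' @param cfg a [kernel_config()].
#' @param exclude optional integer point indices barred from the neighbour
#'   search (leave-one-out).
#' @return An `initial_vector`: list with `v` (length-m probabilities,
#'   summing to 1, zero on dead clusters) and `support` (cluster ids with
#'   positive mass).  Errors with class `progmapper_no_prediction_error`
#'   when all kernel mass falls in dead clusters.
#' @export
initial_vector <- function(x, cloud, graph, model, cfg = kernel_config(),
                           exclude = NULL) {
  stopifnot(inherits(graph, "mapper_graph"),
            inherits(model, "transition_model"))
  cloud <- as.matrix(cloud)
  n_avail <- nrow(cloud) - length(unique(exclude))
  if (n_avail < cfg$mu)
    abort("cloud minus exclusions has fewer than mu points",
          "progmapper_config_error")
  nn <- nearest_neighbours(as.numeric(x), cloud, cfg$mu, exclude)
  w <- exp(-nn$dist2 / cfg$sigma^2)
  if (sum(w) == 0) w <- rep(1, length(w))  # all neighbours far: uniform
  w <- w / sum(w)                          # the constant c of the kernel
  m <- length(model$E)
  v <- numeric(m)
  for (k in seq_along(nn$idx)) {
    cls <- graph$point_clusters[[nn$idx[k]]]
    if (length(cls) == 0) {
      warning("a neighbour belongs to no cluster; its mass is skipped")
      next
    }
    v[cls] <- v[cls] + w[k] / length(cls)
  }
  v[!model$live] <- 0
  if (sum(v) <= 0)
    abort("all kernel mass lies in dead clusters; no prediction possible",
          "progmapper_no_prediction_error")
  v <- v / sum(v)
  structure(list(v = v, support = which(v > 0)), class = "initial_vector")
}

#' Predict the next-year score of a query point
#'
#' One Markov step from the kernel-weighted initial vector, then the
#' expectation of the cluster score expectations:
#' `p(x) = sum_j (v M)[j] E[j]`.  The result is a convex combination of the
#' `E[j]`, hence always within their range.
#'
#' @inheritParams initial_vector
#' @return predicted score (normalized scale).
#' @export
predict_score <- function(x, cloud, graph, model, cfg = kernel_config(),
                          exclude = NULL) {
  iv <- initial_vector(x, cloud, graph, model, cfg, exclude)
  v_next <- as.numeric(iv$v %*% model$M)
  sum(v_next * model$E)
}

# rank-1 leave-one-out correction: remove the pair (x0, y0) from the arrow
# counts and rebuild only the affected rows of M (dead rows fall back to
# identity, live flags updated)
adjust_model_loo <- function(model, graph, x0, y0) {
  ci <- graph$point_clusters[[x0]]
  cj <- graph$point_clusters[[y0]]
  if (length(ci) == 0 || length(cj) == 0) return(model)
  counts <- model$counts
  for (i in ci) counts[i, cj] <- counts[i, cj] - 1L
  row_totals <- model$row_totals
  row_totals[ci] <- row_totals[ci] - length(cj)
  for (i in ci) {
    if (row_totals[i] > 0) {
      model$M[i, ] <- counts[i, ] / row_totals[i]
      model$live[i] <- TRUE
    } else {
      model$M[i, ] <- 0
      model$M[i, i] <- 1
      model$live[i] <- FALSE
    }
  }
  model$counts <- counts
  model$row_totals <- row_totals
  model
}

#' Leave-one-out evaluation of the prediction model
#'
#' For every pair (x0, y0), the next-year score of x0 is predicted with x0
#' excluded from the neighbour-candidate cloud; in the default
#' `"adjusted"` mode the pair is additionally removed from the arrow counts
#' of the evaluated chain (a cheap rank-1 correction closing the two direct
#' leakage paths), and in `"rebuild"` mode the whole mapper graph and chain
#' are rebuilt without x0 (slow; for small clouds).  `"neighbors"` only
#' excludes x0 from the neighbour search.
#'
#' @param pairs a [pair_set()].
#' @param cloud numeric matrix of the point cloud.
#' @param graph,model mapper graph and transition model built on `cloud`.
#' @param cfg a [kernel_config()].
#' @param tolerance hit-in tolerance on the normalized scale (default
#'   [normalized_tolerance()] of 5 points on range 80 = 0.0625).
#' @param scores per-point target score (needed to read off the actual
#'   next-year value); defaults to `attr(model, "scores")` if present.
#' @param mode leave-one-out scope, see above.
#' @param table,filter_names,cover,cluster only for `mode = "rebuild"`:
#'   ingredients to rebuild the graph.
#' @return An `eval_report`: list with `med_type`, `n` (evaluated pairs),
#'   `n_failed` (no-prediction pairs, excluded), `r2`, `mean_error` (signed),
#'   `mae_abs`, `mse`, `max_error`, `hit_in_pct`, and `predictions`
#'   (data.frame of per-pair actual/predicted values).
#' @export
loo_evaluate <- function(pairs, cloud, graph, model, cfg = kernel_config(),
                         tolerance = normalized_tolerance(), scores = NULL,
                         mode = c("adjusted", "neighbors", "rebuild"),
                         table = NULL, filter_names = c("updrs3", "age"),
                         cover = cover_spec(), cluster = cluster_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(pairs, "pair_set"))
  if (nrow(pairs$pairs) < 2)
    abort("need at least 2 pairs", "progmapper_config_error")
  if (is.null(scores)) abort("scores required", "progmapper_config_error")
  pred <- act <- numeric(0)
  rows <- integer(0)
  n_failed <- 0L
  for (r in seq_len(nrow(pairs$pairs))) {
    x0 <- pairs$pairs[r, 1]
    y0 <- pairs$pairs[r, 2]
    res <- tryCatch({
      if (mode == "rebuild") {
        keep <- setdiff(seq_len(nrow(cloud)), x0)
        sub <- table
        sub$data <- sub$data[keep, , drop = FALSE]
        g2 <- build_mapper_graph(sub, filter_names, cover, cluster)
        ps2 <- build_pair_sets(sub)[[as.character(pairs$med_type)]]
        m2 <- build_transition_model(g2, ps2, scores[keep])
        predict_score(cloud[x0, ], cloud[keep, , drop = FALSE], g2, m2, cfg)
      } else {
        m_use <- if (mode == "adjusted")
          adjust_model_loo(model, graph, x0, y0) else model
        predict_score(cloud[x0, ], cloud, graph, m_use, cfg, exclude = x0)
      }
    }, progmapper_no_prediction_error = function(e) NA_real_)
    if (is.na(res)) { n_failed <- n_failed + 1L; next }
    pred <- c(pred, res)
    act <- c(act, scores[y0])
    rows <- c(rows, r)
  }
  if (length(pred) == 0)
    abort("all pairs failed to produce a prediction",
          "progmapper_no_prediction_error")
  err <- pred - act
  ss_tot <- sum((act - mean(act))^2)
  r2 <- if (ss_tot > 0) 1 - sum(err^2) / ss_tot else NA_real_
  structure(list(
    med_type = pairs$med_type, n = length(pred), n_failed = n_failed,
    r2 = r2, mean_error = mean(err), mae_abs = mean(abs(err)),
    mse = mean(err^2), max_error = max(abs(err)),
    hit_in_pct = 100 * mean(abs(err) <= tolerance),
    tolerance = tolerance,
    predictions = data.frame(pair = rows, actual = act, predicted = pred,
                             abs_error = abs(err),
                             hit = abs(err) <= tolerance)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> med_type %d: n=%d (failed %d)  R2=%.3f  mean_err=%.4g  MAE=%.4g  MSE=%.4g  max=%.4g  hit-in=%.1f%%\n",
    x$med_type, x$n, x$n_failed, x$r2, x$mean_error, x$mae_abs, x$mse,
    x$max_error, x$hit_in_pct))
  invisible(x)
}

#' Normalized hit-in tolerance
#'
#' A clinical tolerance of `points` absolute score points, mapped to the
#' normalized `[0, 1]` scale of a score with range `range`:
#' e.g. 5 points on a range of 80 gives 0.0625.
#'
#' @param points absolute-score tolerance (default 5).
#' @param range score range used in normalization (default 80).
#' @return `points / range`.
#' @export
normalized_tolerance <- function(points = 5, range = 80) points / range

#' Grid search over cover parameters
#'
#' Rebuilds the mapper graph and transition model for every cover spec in
#' the grid, runs the leave-one-out evaluation and ranks specs by hit-in
#' percentage (ties by R2), mirroring parameter selection by prediction
#' precision.
#'
#' @param grid list of [cover_spec()] objects.
#' @param table normalized [visit_table()].
#' @param pairs a [pair_set()].
#' @param cfg a [kernel_config()].
#' @param target score feature name.
#' @param filter_names,cluster mapper settings.
#' @param tolerance hit-in tolerance.
#' @return list with `best` (the winning [cover_spec()]) and `results`
#'   (data.frame, one row per spec, ranked).
#' @export
tune_cover_parameters <- function(grid, table, pairs, cfg = kernel_config(),
                                  target = "updrs3",
                                  filter_names = c("updrs3", "age"),
                                  cluster = cluster_config(),
                                  tolerance = normalized_tolerance()) {
  if (length(grid) == 0) abort("empty grid", "progmapper_config_error")
  scores <- table$data[[target]]
  cloud <- feature_matrix(table)
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    cov <- grid[[g]]
    graph <- build_mapper_graph(table, filter_names, cov, cluster)
    model <- build_transition_model(graph, pairs, scores)
    rep <- loo_evaluate(pairs, cloud, graph, model, cfg, tolerance,
                        scores = scores)
    rows[[g]] <- data.frame(spec = g, n1 = cov$n1, n2 = cov$n2, p = cov$p,
                            n = rep$n, r2 = rep$r2,
                            hit_in_pct = rep$hit_in_pct, mse = rep$mse)
  }
  results <- do.call(rbind, rows)
  results <- results[order(-results$hit_in_pct, -results$r2), , drop = FALSE]
  rownames(results) <- NULL
  list(best = grid[[results$spec[1]]], results = results)
}
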