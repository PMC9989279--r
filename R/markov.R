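#' Count progression arrows between mapper clusters
#'
#' Each progression pair (x, y) contributes one arrow from every cluster
#' containing x to every cluster containing y — clusters overlap, so a single
#' pair can feed several matrix cells.  A pair whose endpoint lies in no
#' cluster is skipped (and counted in the `skipped` attribute).
#'
#' @param graph a [build_mapper_graph()] result.
#' @param pairs a [pair_set()].
#' @return m x m integer matrix of arrow counts; `attr(, "skipped")` holds
#'   the number of pairs dropped for lack of cluster membership.
#' @export
count_arrows <- function(graph, pairs) {
  stopifnot(inherits(graph, "mapper_graph"), inherits(pairs, "pair_set"))
  m <- n_clusters(graph)
  counts <- matrix(0L, m, m)
  skipped <- 0L
  for (r in seq_len(nrow(pairs$pairs))) {
    ci <- graph$point_clusters[[pairs$pairs[r, 1]]]
    cj <- graph$point_clusters[[pairs$pairs[r, 2]]]
    if (length(ci) == 0 || length(cj) == 0) {
      skipped <- skipped + 1L
      next
    }
    for (i in ci) counts[i, cj] <- counts[i, cj] + 1L
  }
  if (skipped > 0)
    message(sprintf("count_arrows: skipped %d pair(s) with an endpoint in no cluster",
                    skipped))
  attr(counts, "skipped") <- skipped
  counts
}

#' Estimate the per-medication Markov chain on mapper clusters
#'
#' Row i of the transition matrix is the empirical distribution of arrow
#' destinations out of cluster i, i.e. `M[i, j] = count[i, j] / sum(count[i, ])`.
#' A cluster that is the source of no arrow is "dead": its row is the
#' identity row (the chain is absorbed there), and prediction assigns it zero
#' initial probability.  Cluster score expectations `E[j]` are the mean
#' target score over the cluster's members, each visit counted once per
#' cluster it belongs to.
#'
#' @param graph a [build_mapper_graph()] result.
#' @param pairs a [pair_set()].
#' @param scores numeric vector: per-point target score (same indexing as
#'   the table the graph was built from).
#' @return A `transition_model`: list with `med_type`, `M` (row-stochastic
#'   m x m), `E` (per-cluster expectations), `live` (logical), `counts`,
#'   `row_totals`.
#' @export
build_transition_model <- function(graph, pairs, scores) {
  stopifnot(inherits(graph, "mapper_graph"))
  if (length(scores) != graph$n_points)
    abort("scores must have one value per point", "progmapper_config_error")
  m <- n_clusters(graph)
  counts <- count_arrows(graph, pairs)
  row_totals <- rowSums(counts)
  live <- row_totals > 0
  M <- diag(m)
  for (i in which(live)) M[i, ] <- counts[i, ] / row_totals[i]
  E <- vapply(graph$clusters, function(cl) mean(scores[cl$members]),
              numeric(1))
  structure(list(med_type = pairs$med_type, M = M, E = E, live = live,
                 counts = counts, row_totals = row_totals),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> med_type %d: %d clusters, %d live\n",
              x$med_type, length(x$E), sum(x$live)))
  invisible(x)
}

#' Per-cluster visit counts of one medication type
#'
#' `d[j]` = number of visits of the given medication type lying in cluster j
#' (a visit in several clusters counts once in each).
#'
#' @param graph a [build_mapper_graph()] result.
#' @param table the [visit_table()] the graph was built from.
#' @param med_type integer 0--7.
#' @param per_patient if `TRUE`, count distinct patients instead of visits.
#' @return integer vector of length m.
#' @export
cluster_type_counts <- function(graph, table, med_type, per_patient = FALSE) {
  stopifnot(inherits(graph, "mapper_graph"), inherits(table, "visit_table"))
  sel <- table$data$med_type == med_type
  vapply(graph$clusters, function(cl) {
    mem <- cl$members[sel[cl$members]]
    if (per_patient) length(unique(table$data$patient_id[mem]))
    else length(mem)
  }, numeric(1))
}

#' Expected one-year score growth under a medication type
#'
#' The occupancy distribution `w = d / sum(d)` gives the probability that a
#' visit of this type lies in each cluster; the per-cluster growth is the
#' expected change of cluster score expectation after one Markov step,
#' `delta[j] = sum_l M[j, l] (E[l] - E[j])`; the overall expected growth is
#' `delta = sum_j w[j] delta[j]`.
#'
#' @param model a [build_transition_model()] result.
#' @param d per-cluster visit counts for this medication type, from
#'   [cluster_type_counts()].
#' @return A `growth_report`: list with `med_type`, `w`, `delta_j`, `delta`.
#' @export
expected_growth <- function(model, d) {
  stopifnot(inherits(model, "transition_model"))
  if (length(d) != length(model$E))
    abort("d must have one count per cluster", "progmapper_config_error")
  if (sum(d) <= 0)
    abort("no visits of this medication type in any cluster",
          "progmapper_no_visits_error")
  w <- d / sum(d)
  delta_j <- as.numeric(model$M %*% model$E) - model$E
  delta <- sum(w * delta_j)
  structure(list(med_type = model$med_type, w = w, delta_j = delta_j,
                 delta = delta),
            class = "growth_report")
}

#' @export
print.growth_report <- function(x, ...) {
  cat(sprintf("<growth_report> med_type %d: expected growth %.5f (normalized)\n",
              x$med_type, x$delta))
  invisible(x)
}

#' Un-biased medication-effect comparison
#'
#' Counterfactual: what growth would the type-i group have experienced
#' un-medicated?  Apply the un-medicated chain (type 0) to the type-i
#' occupancy distribution p:
#' `delta_prime = sum_j sum_k p[j] M0[j, k] (E[k] - E[j])`.
#' The difference `delta_prime - delta_i` measures the benefit of the
#' medication in reducing score growth.
#'
#' @param model_i transition model of the medicated group.
#' @param model_0 transition model of the un-medicated group (type 0); must
#'   be built on the same mapper graph.
#' @param p occupancy distribution of the type-i group over clusters
#'   (will be normalized).
#' @return list with `delta` (actual growth of type i under p),
#'   `delta_prime` (counterfactual un-medicated growth) and `effect`
#'   (`delta_prime - delta`).
#' @export
unbiased_effect <- function(model_i, model_0, p) {
  stopifnot(inherits(model_i, "transition_model"),
            inherits(model_0, "transition_model"))
  if (length(model_i$E) != length(model_0$E))
    abort("models were built on different graphs", "progmapper_config_error")
  if (length(p) != length(model_i$E))
    abort("p must have one entry per cluster", "progmapper_config_error")
  if (sum(p) <= 0) abort("p must have positive mass", "progmapper_config_error")
  p <- p / sum(p)
  g_i <- as.numeric(model_i$M %*% model_i$E) - model_i$E
  g_0 <- as.numeric(model_0$M %*% model_0$E) - model_0$E
  delta <- sum(p * g_i)
  delta_prime <- sum(p * g_0)
  list(med_type = model_i$med_type, delta = delta, delta_prime = delta_prime,
       effect = delta_prime - delta)
}

#' Per-type growth and medication-effect table
#'
#' Convenience wrapper running the whole Markov stage for every medication
#' type with at least one pair: builds per-type transition models, expected
#' growth, and (for types other than 0, when type 0 is available) the
#' counterfactual un-medicated growth.  Growth is reported both on the
#' normalized scale and de-normalized by `score_range` (absolute points).
#'
#' @param table the normalized [visit_table()].
#' @param graph the [build_mapper_graph()] result.
#' @param pair_sets list from [build_pair_sets()].
#' @param target score feature name.
#' @param score_range multiplier mapping normalized growth back to absolute
#'   score points (the fitted max - min of the target).
#' @return data.frame with one row per represented type: `med_type`,
#'   `n_pairs`, `delta`, `delta_prime`, `effect` (normalized) and
#'   `delta_abs`, `delta_prime_abs`, `effect_abs`.
#' @export
growth_table <- function(table, graph, pair_sets, target = "updrs3",
                         score_range = 80) {
  scores <- table$data[[target]]
  models <- lapply(pair_sets, function(ps)
    if (nrow(ps$pairs) > 0) build_transition_model(graph, ps, scores) else NULL)
  model_0 <- models[["0"]]
  rows <- list()
  for (t in names(pair_sets)) {
    model <- models[[t]]
    if (is.null(model)) next
    d <- cluster_type_counts(graph, table, as.integer(t))
    if (sum(d) == 0) next
    gr <- expected_growth(model, d)
    dp <- NA_real_
    if (!is.null(model_0) && t != "0")
      dp <- unbiased_effect(model, model_0, gr$w)$delta_prime
    rows[[t]] <- data.frame(
      med_type = as.integer(t), n_pairs = nrow(pair_sets[[t]]$pairs),
      delta = gr$delta, delta_prime = dp, effect = dp - gr$delta,
      delta_abs = gr$delta * score_range, delta_prime_abs = dp * score_range,
      effect_abs = (dp - gr$delta) * score_range)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
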