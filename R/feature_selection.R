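#' Rank features by correlation with a target score
#'
#' Features are ordered by the absolute value of their Pearson correlation
#' with the target column, descending; coefficients are reported signed.
#' A constant feature gets `r = 0` with a warning.
#'
#' @param table a [visit_table()].
#' @param target name of the target feature (e.g. `"updrs3"`).
#' @return data.frame with columns `feature` and `r`, sorted by `|r|`
#'   descending (the target itself is excluded).
#' @export
rank_by_correlation <- function(table, target = "updrs3") {
  stopifnot(inherits(table, "visit_table"))
  if (!target %in% table$feature_names)
    abort(sprintf("target '%s' is not a feature", target),
          "progmapper_config_error")
  if (nrow(table$data) < 3)
    abort("need at least 3 rows", "progmapper_config_error")
  y <- table$data[[target]]
  others <- setdiff(table$feature_names, target)
  r <- vapply(others, function(f) {
    v <- table$data[[f]]
    if (sd(v) == 0 || sd(y) == 0) {
      warning(sprintf("feature '%s' is constant; correlation set to 0", f))
      return(0)
    }
    cor(v, y)
  }, numeric(1))
  out <- data.frame(feature = others, r = unname(r),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$feature), , drop = FALSE]
}

# lexicographic (H0, H1) diagram dissimilarity between a cloud and the same
# cloud with one column removed.  H0 carries the decision: on tabular
# clinical clouds the load-bearing topology is the component (cluster)
# structure, and degree-1 bars at desk scale are sampling-scale artifacts
# that fail to order candidate removals.  H1 breaks ties.
cloud_dissimilarity <- function(base_diag, cand_diag, method, q) {
  c(h0 = diagram_distance(base_diag, cand_diag, dimension = 0,
                          method = method, q = q),
    h1 = diagram_distance(base_diag, cand_diag, dimension = 1,
                          method = method, q = q))
}

#' Topology-preserving greedy feature elimination
#'
#' Implements persistence-based backward elimination: at every step, for each
#' remaining removable feature, compare the Vietoris-Rips persistence of the
#' current cloud with that of the cloud with the feature dropped; remove the
#' feature whose removal perturbs the diagrams least.  Stop when even the
#' least-perturbing removal changes the topology by more than `threshold`
#' (or when `k` features remain, if `k` is given).  The intuition: a feature
#' whose removal leaves the persistent homology essentially unchanged carries
#' no independent geometric information.
#'
#' Within one step, all candidate comparisons reuse the same subsample of
#' points, so differences reflect the removed feature only (a paired
#' comparison).  Dissimilarity is the bottleneck (or Wasserstein) distance on
#' degree-0 finite bars — the component structure, which carries the
#' topology of tabular clinical clouds — with the degree-1 distance breaking
#' ties.
#'
#' @param table a normalized [visit_table()].
#' @param candidates ordered list of features eligible for the procedure
#'   (default: all features).
#' @param protected features that are never removed (default the two mapper
#'   filter axes, `"age"` and `"updrs3"`).
#' @param threshold stop when the minimal dissimilarity (H0 component)
#'   exceeds this value; must be positive.  `Inf` eliminates every removable
#'   feature.
#' @param k optional target feature count: stop once `k` features remain
#'   (overrides `threshold`-based stopping when reached first).
#' @param method,q diagram distance, see [diagram_distance()].
#' @param maxdim maximal homology degree (0 or 1).
#' @param subsample subsample size per step (see [rips_persistence()]).
#' @param seed RNG seed; the subsample of step `s` is drawn under
#'   `seed + s - 1`, so reruns are bit-reproducible.
#' @return A `selection_trace`: list with `trace` (data.frame
#'   `removed_feature`, `distance` (H0), `h1_distance` in removal order) and
#'   `selected` (the surviving features).
#' @export
eliminate_features <- function(table, candidates = NULL,
                               protected = c("age", "updrs3"),
                               threshold = 0.17, k = NULL,
                               method = c("bottleneck", "wasserstein"), q = 2,
                               maxdim = 1, subsample = 200, seed = 1L) {
  stopifnot(inherits(table, "visit_table"))
  method <- match.arg(method)
  if (!is.null(threshold) && threshold <= 0)
    abort("threshold must be positive", "progmapper_config_error")
  candidates <- candidates %||% table$feature_names
  if (!all(candidates %in% table$feature_names))
    abort("candidates must be features of the table", "progmapper_config_error")
  current <- candidates
  x_all <- feature_matrix(table, candidates)
  removed <- character(0)
  dists <- h1_dists <- numeric(0)
  step <- 0L
  repeat {
    step <- step + 1L
    removable <- setdiff(current, protected)
    if (length(removable) == 0) break
    if (!is.null(k) && length(current) <= k) break
    # one shared subsample per step: paired comparison across candidates
    n <- nrow(x_all)
    idx <- seq_len(n)
    if (!is.null(subsample) && subsample < n)
      idx <- sort(with_seed(seed + step - 1L, sample.int(n, subsample)))
    xs <- x_all[idx, current, drop = FALSE]
    base_diag <- rips_persistence(xs, maxdim = maxdim)
    d <- t(vapply(removable, function(f) {
      cand <- rips_persistence(xs[, setdiff(current, f), drop = FALSE],
                               maxdim = maxdim)
      cloud_dissimilarity(base_diag, cand, method, q)
    }, numeric(2)))
    best <- order(d[, "h0"], d[, "h1"], removable)[1]
    if (is.null(k) && d[best, "h0"] > threshold) break
    removed <- c(removed, removable[best])
    dists <- c(dists, d[best, "h0"])
    h1_dists <- c(h1_dists, d[best, "h1"])
    current <- setdiff(current, removable[best])
  }
  structure(
    list(trace = data.frame(removed_feature = removed, distance = dists,
                            h1_distance = h1_dists,
                            stringsAsFactors = FALSE),
         selected = current),
    class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> removed %d feature(s), %d selected\n",
              nrow(x$trace), length(x$selected)))
  if (nrow(x$trace) > 0) print(x$trace)
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection trace as JSON
#'
#' @param trace a `selection_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  jsonlite::write_json(list(trace = trace$trace, selected = trace$selected),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
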