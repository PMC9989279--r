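# Exporters for the artifact's external interfaces: GraphML / JSON for the
# mapper graph, CSV + JSON sidecar for transition models, CSV / JSON for
# growth and evaluation tables.

#' Export a mapper graph
#'
#' `write_mapper_graphml()` writes the 1-skeleton as GraphML with per-cluster
#' `size` and `mean_score` attributes; `write_mapper_json()` writes the full
#' structure (clusters with member indices, edges, cover spec).
#'
#' @param graph a [build_mapper_graph()] result.
#' @param path output path.
#' @param scores optional per-point score used for the `mean_score` node
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_mapper_graphml <- function(graph, path, scores = NULL) {
  stopifnot(inherits(graph, "mapper_graph"))
  m <- n_clusters(graph)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (nrow(graph$edges) > 0)
    g <- igraph::add_edges(g, t(graph$edges))
  igraph::V(g)$name <- as.character(seq_len(m))
  igraph::V(g)$size <- vapply(graph$clusters,
                              function(cl) length(cl$members), numeric(1))
  if (!is.null(scores))
    igraph::V(g)$mean_score <- vapply(graph$clusters,
                                      function(cl) mean(scores[cl$members]),
                                      numeric(1))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_mapper_graphml
#' @export
write_mapper_json <- function(graph, path) {
  stopifnot(inherits(graph, "mapper_graph"))
  doc <- list(
    filter_names = graph$filter_names,
    cover = unclass(graph$cover),
    n_points = graph$n_points,
    clusters = lapply(graph$clusters, function(cl)
      list(id = cl$id, bin_id = cl$bin_id, members = cl$members)),
    edges = if (nrow(graph$edges) > 0) apply(graph$edges, 1, as.list)
            else list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a transition model
#'
#' The matrix goes to CSV with cluster ids as header; expectations, live
#' flags and the medication type go to a JSON sidecar (`<path>.json` unless
#' given).
#'
#' @param model a [build_transition_model()] result.
#' @param path CSV output path.
#' @param sidecar JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_transition_model <- function(model, path,
                                   sidecar = paste0(path, ".json")) {
  stopifnot(inherits(model, "transition_model"))
  M <- model$M
  colnames(M) <- paste0("C", seq_len(ncol(M)))
  write.csv(M, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(med_type = model$med_type, E = model$E, live = model$live),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a per-type growth table
#'
#' @param tab a data.frame from [growth_table()].
#' @param path output path (`.json` extension switches to JSON).
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(tab, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  else write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export evaluation reports
#'
#' `write_eval_reports()` writes one CSV row per medication type
#' (R2, signed mean error, MAE, MSE, max error, hit-in percentage);
#' `write_predictions()` writes the per-pair predictions of one report.
#'
#' @param reports list of `eval_report` objects.
#' @param path output path (`.json` switches to JSON).
#' @return `path`, invisibly.
#' @export
write_eval_reports <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(med_type = r$med_type, n = r$n, n_failed = r$n_failed,
               r2 = r$r2, mean_error = r$mean_error, mae_abs = r$mae_abs,
               mse = r$mse, max_error = r$max_error,
               hit_in_pct = r$hit_in_pct)))
  rownames(df) <- NULL
  if (grepl("\\.json$", path))
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  else write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eval_reports
#' @param report a single `eval_report`.
#' @export
write_predictions <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  write.csv(report$predictions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
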