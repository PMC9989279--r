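#' Fit a per-feature min-max normalization
#'
#' Records the observed minimum and maximum of every feature so that
#' `x -> (x - min) / (max - min)` maps the fitting data into `[0, 1]`.
#' Selected features may additionally carry a clamp value on the normalized
#' scale: after rescaling, values above the clamp are capped at it.  Clamping
#' the motor score (e.g. at 0.7) limits the influence of the few most severe
#' visits on the point-cloud geometry.
#'
#' @param table a [visit_table()].
#' @param clamp optional named list/vector: feature name -> clamp value in
#'   `(0, 1]`, applied after min-max rescaling.
#' @return A `normalization_spec` object.
#' @export
fit_normalization <- function(table, clamp = NULL) {
  stopifnot(inherits(table, "visit_table"))
  mins <- maxs <- setNames(numeric(length(table$feature_names)),
                           table$feature_names)
  for (f in table$feature_names) {
    v <- table$data[[f]]
    mins[f] <- min(v); maxs[f] <- max(v)
    if (maxs[f] <= mins[f])
      abort(sprintf("feature '%s' is constant; cannot normalize", f),
            "progmapper_degenerate_feature_error")
  }
  clamp <- as.list(clamp %||% list())
  if (length(clamp) > 0) {
    if (!all(names(clamp) %in% table$feature_names))
      abort("clamp names must be feature names", "progmapper_config_error")
    cv <- unlist(clamp)
    if (any(cv <= 0 | cv > 1))
      abort("clamp values must lie in (0, 1]", "progmapper_config_error")
  }
  structure(list(min = mins, max = maxs, clamp = clamp),
            class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat(sprintf("<normalization_spec> %d features", length(x$min)))
  if (length(x$clamp) > 0)
    cat(sprintf("; clamped: %s",
                paste(sprintf("%s@%g", names(x$clamp), unlist(x$clamp)),
                      collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Apply a fitted normalization to a visit table
#'
#' Values of new data falling outside the fitted `[min, max]` are clipped
#' into `[0, 1]` with a warning rather than failing, so a model fitted on one
#' cohort can score unseen patients.
#'
#' @param table a [visit_table()].
#' @param spec a spec from [fit_normalization()].
#' @return A normalized [visit_table()] (flag set, all features in `[0, 1]`).
#' @export
apply_normalization <- function(table, spec) {
  stopifnot(inherits(table, "visit_table"), inherits(spec, "normalization_spec"))
  if (!all(table$feature_names %in% names(spec$min)))
    abort("normalization spec does not cover all features",
          "progmapper_config_error")
  df <- table$data
  n_clipped <- 0L
  for (f in table$feature_names) {
    z <- (df[[f]] - spec$min[[f]]) / (spec$max[[f]] - spec$min[[f]])
    out <- z < 0 | z > 1
    n_clipped <- n_clipped + sum(out)
    z <- pmin(pmax(z, 0), 1)
    cl <- spec$clamp[[f]]
    if (!is.null(cl)) z <- pmin(z, cl)
    df[[f]] <- z
  }
  if (n_clipped > 0)
    warning(sprintf("%d value(s) outside the fitted range were clipped into [0, 1]",
                    n_clipped))
  visit_table(df, table$feature_names, normalized = TRUE)
}

#' Serialize / restore a normalization spec as JSON
#'
#' @param spec a `normalization_spec`.
#' @param path file path.
#' @return `path` invisibly; `read_normalization_spec()` returns the spec.
#' @export
write_normalization_spec <- function(spec, path) {
  stopifnot(inherits(spec, "normalization_spec"))
  jsonlite::write_json(
    list(min = as.list(spec$min), max = as.list(spec$max), clamp = spec$clamp),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_spec
#' @export
read_normalization_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = unlist(x$min), max = unlist(x$max),
                 clamp = as.list(x$clamp)),
            class = "normalization_spec")
}
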