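#' Longitudinal visit tables
#'
#' A `visit_table` holds one row per patient-visit: a patient identifier, a
#' 0-based study-year index, a medication-type code in 0--7 and a fixed set of
#' numeric clinical features (e.g. age, UPDRS III, non-motor scores).  It is
#' the point cloud every downstream stage (feature selection, mapper graph,
#' Markov chain, prediction) operates on.
#'
#' @param data data.frame with columns `patient_id`, `year`, `med_type` and
#'   one numeric column per feature.
#' @param feature_names character vector naming the feature columns, in order.
#' @param normalized logical; `TRUE` once all features lie in `[0, 1]`.
#' @return An object of class `visit_table`.
#' @export
visit_table <- function(data, feature_names, normalized = FALSE) {
  required <- c("patient_id", "year", "med_type")
  missing_cols <- setdiff(c(required, feature_names), names(data))
  if (length(missing_cols) > 0)
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          "progmapper_schema_error")
  data$patient_id <- as.character(data$patient_id)
  data$year <- as.integer(data$year)
  data$med_type <- as.integer(data$med_type)
  if (any(is.na(data$med_type)) || any(data$med_type < 0L | data$med_type > 7L))
    abort("med_type must be an integer in 0..7", "progmapper_schema_error")
  for (f in feature_names) {
    v <- data[[f]]
    if (!is.numeric(v))
      abort(sprintf("feature '%s' is not numeric", f), "progmapper_parse_error")
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      abort(sprintf("feature '%s' has a non-finite value at row %d", f, bad),
            "progmapper_parse_error")
    }
  }
  key <- paste(data$patient_id, data$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicate (patient_id, year) pair: (%s)",
                  gsub("\r", ", year ", dup)),
          "progmapper_integrity_error")
  }
  structure(
    list(data = data[, c(required, feature_names), drop = FALSE],
         feature_names = as.character(feature_names),
         normalized = isTRUE(normalized)),
    class = "visit_table"
  )
}

#' @export
print.visit_table <- function(x, ...) {
  cat(sprintf("<visit_table> %d visits, %d patients, %d features%s\n",
              nrow(x$data), length(unique(x$data$patient_id)),
              length(x$feature_names),
              if (x$normalized) " (normalized)" else ""))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.visit_table <- function(x) c(nrow(x$data), length(x$feature_names))

#' Extract the numeric feature matrix of a visit table
#'
#' @param table a [visit_table()].
#' @param features optional subset of feature names (default: all).
#' @return numeric matrix, one row per visit.
#' @export
feature_matrix <- function(table, features = NULL) {
  stopifnot(inherits(table, "visit_table"))
  features <- features %||% table$feature_names
  as.matrix(table$data[, features, drop = FALSE])
}

#' Read a visit table from a delimited text file
#'
#' The delimiter is auto-detected from the extension (`.tsv`/`.txt` = tab,
#' otherwise comma).  Column roles are given by `schema`; rows with a missing
#' value in any mapped feature are dropped with a message (no imputation).
#'
#' @param path path to a CSV/TSV file with one header row.
#' @param schema named list with entries `patient_col`, `year_col`, `med_col`
#'   and `feature_cols` (named character vector or plain character vector of
#'   column names; names, if given, become the feature names).
#' @return A [visit_table()]; row order of the file is preserved.
#' @export
read_visit_table <- function(path, schema) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "progmapper_io_error")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  needed <- c(schema$patient_col, schema$year_col, schema$med_col,
              unname(schema$feature_cols))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          "progmapper_schema_error")
  fcols <- schema$feature_cols
  fnames <- if (is.null(names(fcols)) || any(names(fcols) == ""))
    unname(fcols) else names(fcols)
  df <- data.frame(patient_id = as.character(raw[[schema$patient_col]]),
                   year = raw[[schema$year_col]],
                   med_type = raw[[schema$med_col]],
                   stringsAsFactors = FALSE)
  for (k in seq_along(fcols)) {
    v <- raw[[unname(fcols)[k]]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad) > 0)
        abort(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                      v[bad[1]], unname(fcols)[k], bad[1]),
              "progmapper_parse_error")
      v <- conv
    }
    df[[fnames[k]]] <- as.numeric(v)
  }
  keep <- stats::complete.cases(df[, fnames, drop = FALSE])
  if (any(!keep))
    message(sprintf("dropped %d row(s) with missing feature values",
                    sum(!keep)))
  visit_table(df[keep, , drop = FALSE], fnames)
}

#' Write a visit table as CSV
#'
#' @param table a [visit_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_visit_table <- function(table, path) {
  stopifnot(inherits(table, "visit_table"))
  write.csv(table$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default schema for files written by [write_visit_table()]
#'
#' @param feature_cols feature column names.
#' @return schema list for [read_visit_table()].
#' @export
visit_schema <- function(feature_cols) {
  list(patient_col = "patient_id", year_col = "year", med_col = "med_type",
       feature_cols = feature_cols)
}
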