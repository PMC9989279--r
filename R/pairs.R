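#' Build per-medication-type progression pair sets
#'
#' A progression pair joins two visits of the same patient exactly one study
#' year apart; it represents a one-year disease progression observed under a
#' medication regimen.  Pairs are grouped by the medication type of (by
#' default) the current-year visit, giving one `pair_set` per type 0--7.
#' Visits separated by more than one year (a skipped visit) yield no pair.
#'
#' @param table a [visit_table()].
#' @param type_from `"current"` (default) or `"next"`: which visit's
#'   medication code labels the pair.
#' @return A list of 8 `pair_set` objects, named `"0"` .. `"7"`.  Each has
#'   fields `med_type` and `pairs`, a 2-column integer matrix of
#'   (current, next) row indices into `table$data`.  Empty sets are legal.
#' @export
build_pair_sets <- function(table, type_from = c("current", "next")) {
  stopifnot(inherits(table, "visit_table"))
  type_from <- match.arg(type_from)
  df <- table$data
  cur <- next_ <- integer(0)
  idx_by_patient <- split(seq_len(nrow(df)), df$patient_id)
  for (rows in idx_by_patient) {
    yr <- df$year[rows]
    o <- rows[order(yr)]
    yr <- sort(yr)
    hit <- which(diff(yr) == 1L)
    cur <- c(cur, o[hit])
    next_ <- c(next_, o[hit + 1L])
  }
  o <- order(cur)
  cur <- cur[o]; next_ <- next_[o]
  lab <- if (type_from == "current") df$med_type[cur] else df$med_type[next_]
  out <- lapply(0:7, function(t) {
    sel <- lab == t
    pair_set(t, cbind(current = cur[sel], next_ = next_[sel]))
  })
  names(out) <- as.character(0:7)
  out
}

#' Construct a pair set
#'
#' @param med_type integer 0--7.
#' @param pairs 2-column integer matrix of (current, next) point indices.
#' @return A `pair_set` object.
#' @export
pair_set <- function(med_type, pairs) {
  med_type <- as.integer(med_type)
  if (is.na(med_type) || med_type < 0L || med_type > 7L)
    abort("med_type must be in 0..7", "progmapper_config_error")
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("current", "next_")))
  structure(list(med_type = med_type, pairs = pairs), class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> med_type %d: %d pair(s)\n", x$med_type,
              nrow(x$pairs)))
  invisible(x)
}
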