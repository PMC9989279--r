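#' Vietoris-Rips persistent homology of a point cloud
#'
#' Computes persistence diagrams in homology degrees 0 (connected components)
#' and optionally 1 (loops) of the Vietoris-Rips filtration under Euclidean
#' distance.  The filtration is truncated at the enclosing radius
#' `min_i max_j d(i, j)`, past which the complex is a cone and all homology
#' has died; essential classes are reported truncated at that value with an
#' `essential` flag.
#'
#' @param x numeric matrix (rows = points) or a normalized [visit_table()]
#'   (its feature matrix is used).
#' @param maxdim maximal homology degree, 0 or 1.
#' @param subsample optional integer: number of points to draw (without
#'   replacement, uniformly under `seed`) before computing persistence.
#'   Degree-1 reduction is cubic-ish in the number of points, so large clouds
#'   should be subsampled.
#' @param seed RNG seed for the subsample draw.
#' @return A `persistence_diagrams` object: list with data frames `H0`, `H1`
#'   (columns `birth`, `death`, `essential`) and the truncation `threshold`.
#' @export
rips_persistence <- function(x, maxdim = 1, subsample = NULL, seed = 1L) {
  if (inherits(x, "visit_table")) x <- feature_matrix(x)
  x <- as.matrix(x)
  if (!maxdim %in% c(0, 1))
    abort("maxdim must be 0 or 1", "progmapper_config_error")
  if (!is.null(subsample) && subsample < nrow(x)) {
    if (subsample < 2)
      abort("too few points after subsampling", "progmapper_config_error")
    idx <- with_seed(seed, sample.int(nrow(x), subsample))
    x <- x[sort(idx), , drop = FALSE]
  }
  if (nrow(x) < 2)
    abort("need at least 2 points", "progmapper_config_error")
  res <- .rips_persistence_cpp(as.matrix(dist(x)), as.integer(maxdim))
  as_diag <- function(m) {
    data.frame(birth = m[, 1], death = m[, 2], essential = m[, 3] == 1)
  }
  structure(list(H0 = as_diag(res$H0), H1 = as_diag(res$H1),
                 threshold = res$threshold),
            class = "persistence_diagrams")
}

#' @export
print.persistence_diagrams <- function(x, ...) {
  cat(sprintf("<persistence_diagrams> H0: %d bar(s), H1: %d bar(s), truncated at %.4g\n",
              nrow(x$H0), nrow(x$H1), x$threshold))
  invisible(x)
}

#' Distance between two persistence diagrams
#'
#' Bottleneck (default) or q-Wasserstein distance in one homology degree,
#' under the L-infinity ground metric with diagonal matching.  Both are
#' computed exactly (binary search over matching feasibility, respectively a
#' Hungarian assignment on the diagonal-augmented cost matrix).
#'
#' @param a,b `persistence_diagrams` objects (or plain 2-column matrices of
#'   birth/death pairs).
#' @param dimension homology degree to compare (0 or 1) when diagrams objects
#'   are passed.
#' @param method `"bottleneck"` or `"wasserstein"`.
#' @param q Wasserstein order (ignored for bottleneck).
#' @return a nonnegative number.
#' @export
diagram_distance <- function(a, b, dimension = 1,
                             method = c("bottleneck", "wasserstein"), q = 2) {
  method <- match.arg(method)
  pts <- function(d) {
    if (inherits(d, "persistence_diagrams"))
      d <- d[[paste0("H", dimension)]]
    d <- as.data.frame(d)
    # essential classes are truncation artifacts of the filtration cap;
    # distances compare finite bars only (the standard convention)
    if ("essential" %in% names(d)) d <- d[!d$essential, , drop = FALSE]
    cols <- if (all(c("birth", "death") %in% names(d))) c("birth", "death")
            else 1:2
    m <- cbind(as.numeric(d[[cols[1]]]), as.numeric(d[[cols[2]]]))
    m[m[, 2] > m[, 1], , drop = FALSE]  # zero-persistence points are diagonal
  }
  A <- pts(a); B <- pts(b)
  if (method == "bottleneck") .bottleneck_cpp(A, B)
  else .wasserstein_cpp(A, B, q)
}

#' Export persistence diagrams as CSV
#'
#' One row per bar: `dimension, birth, death, essential`.
#'
#' @param diagrams a `persistence_diagrams` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagrams <- function(diagrams, path) {
  stopifnot(inherits(diagrams, "persistence_diagrams"))
  df <- rbind(
    cbind(dimension = 0, diagrams$H0),
    cbind(dimension = 1, diagrams$H1))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
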