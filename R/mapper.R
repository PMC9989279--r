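#' Cover specification for the 2-D mapper filter
#'
#' The filter image (a rectangle in the plane spanned by the two filter
#' features) is covered by `n1 * n2` overlapping closed boxes: each axis
#' range is split into `n` equal base intervals, then every interval is
#' enlarged symmetrically by `p/2` of the base length per side, so adjacent
#' intervals overlap by the fraction `p` of the base length.
#'
#' @param n1 number of intervals along the first filter axis (the score).
#' @param n2 number of intervals along the second filter axis (age).
#' @param p overlap fraction in `[0, 1)`.
#' @return A `cover_spec` object.
#' @export
cover_spec <- function(n1 = 20, n2 = 40, p = 0.05) {
  if (n1 < 1 || n2 < 1) abort("interval counts must be >= 1",
                              "progmapper_config_error")
  if (p < 0 || p >= 1) abort("overlap p must be in [0, 1)",
                             "progmapper_config_error")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), p = p),
            class = "cover_spec")
}

#' Named cover presets
#'
#' The two settings used for the reference mapper runs: a sparse overlap
#' (`"sparse"`, p = 0.05) and a dense one (`"dense"`, p = 0.3), both on a
#' 20 x 40 interval grid.
#'
#' @param name `"sparse"` or `"dense"`.
#' @return A [cover_spec()].
#' @export
cover_preset <- function(name = c("sparse", "dense")) {
  name <- match.arg(name)
  switch(name,
         sparse = cover_spec(20, 40, 0.05),
         dense  = cover_spec(20, 40, 0.3))
}

# overlapping closed intervals covering [lo, hi] (single axis)
axis_intervals <- function(values, n, p) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) {
    warning("all points equal on one filter axis; using a single degenerate interval")
    return(matrix(c(lo, hi), ncol = 2))
  }
  base <- (hi - lo) / n
  starts <- lo + (seq_len(n) - 1) * base
  cbind(starts - p / 2 * base, starts + base + p / 2 * base)
}

#' Build the overlapping box cover of a filter image
#'
#' @param filter_values numeric matrix of per-point filter coordinates
#'   (1 or 2 columns).
#' @param cover a [cover_spec()] (for 2 columns), or an integer vector of
#'   per-axis interval counts together with `p`.
#' @param p overlap fraction, only used when `cover` is an integer vector.
#' @return A list of boxes; each box is a list with `bin_id` (1-based linear
#'   index, axis 1 fastest), `bounds` (d x 2 matrix) and `members` (point
#'   indices whose filter value lies in the closed box).  Every point lies in
#'   at least one box.
#' @export
build_cover <- function(filter_values, cover, p = NULL) {
  filter_values <- as.matrix(filter_values)
  if (nrow(filter_values) < 1)
    abort("need at least one point", "progmapper_config_error")
  if (inherits(cover, "cover_spec")) {
    n_axis <- c(cover$n1, cover$n2)[seq_len(ncol(filter_values))]
    p <- cover$p
  } else {
    n_axis <- as.integer(cover)
    if (is.null(p)) abort("p required", "progmapper_config_error")
  }
  if (length(n_axis) != ncol(filter_values))
    abort("one interval count per filter axis required",
          "progmapper_config_error")
  ivs <- lapply(seq_along(n_axis), function(a)
    axis_intervals(filter_values[, a], n_axis[a], p))
  grid <- expand.grid(lapply(ivs, function(m) seq_len(nrow(m))))
  boxes <- vector("list", nrow(grid))
  for (b in seq_len(nrow(grid))) {
    inside <- rep(TRUE, nrow(filter_values))
    bounds <- matrix(0, length(n_axis), 2)
    for (a in seq_along(n_axis)) {
      iv <- ivs[[a]][grid[b, a], ]
      bounds[a, ] <- iv
      inside <- inside & filter_values[, a] >= iv[1] & filter_values[, a] <= iv[2]
    }
    boxes[[b]] <- list(bin_id = b, bounds = bounds, members = which(inside))
  }
  boxes
}

#' Clustering configuration for mapper bins
#'
#' Two clusterers are available.  `"dbscan"` (default): density clustering
#' with `min_samples = 1` — i.e. connected components of the
#' mutual-reachability graph at radius `eps` — where `eps` is chosen per bin
#' at the largest gap in the sorted k-nearest-neighbour distances
#' (the k-distance elbow).  With `min_samples = 1` no point is discarded as
#' noise.  `"single"`: single-linkage merged up to the first empty bin of the
#' merge-height histogram (the classic histogram-gap heuristic).
#'
#' @param method `"dbscan"` or `"single"`.
#' @param k neighbour index for the k-distance elbow (dbscan).
#' @param nbins histogram bin count for the gap heuristic (single linkage).
#' @return A `cluster_config` object.
#' @export
cluster_config <- function(method = c("dbscan", "single"), k = 3, nbins = 10) {
  method <- match.arg(method)
  structure(list(method = method, k = as.integer(k), nbins = as.integer(nbins)),
            class = "cluster_config")
}

#' Cluster the points of one mapper bin
#'
#' Partitions the bin's members under Euclidean distance in the full feature
#' space.  Deterministic: cluster order follows the smallest member index.
#'
#' @param x numeric matrix of the bin members' feature vectors.
#' @param config a [cluster_config()].
#' @return list of integer vectors of row indices into `x` (a partition).
#' @export
cluster_bin <- function(x, config = cluster_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) abort("bin is empty", "progmapper_config_error")
  if (n == 1) return(list(1L))
  dm <- as.matrix(dist(x))
  labels <- if (config$method == "dbscan") {
    # k-distance elbow: eps at the largest gap of the sorted k-NN distances
    k <- min(config$k, n - 1L)
    kdist <- sort(apply(dm, 1, function(r) sort(r)[k + 1L]))
    # elbow = a multiplicative jump in the sorted k-distances (a point whose
    # k-th neighbour is in another density regime); additive gaps over-split
    # tight clusters.  Without a pronounced jump the whole bin stays
    # reachable at the largest k-distance.
    eps <- kdist[length(kdist)]
    if (length(kdist) > 1) {
      lo <- kdist[-length(kdist)]
      hi <- kdist[-1]
      ratio <- ifelse(lo > 0, hi / lo, 1)
      if (max(ratio) > 2) eps <- lo[which.max(ratio)]
    }
    # min_samples = 1: clusters are components of the <= eps neighbour graph
    comp_labels(dm <= eps + 1e-12)
  } else {
    hc <- hclust(dist(x), method = "single")
    h <- hc$height
    cut <- max(h)
    if (length(h) > 0 && max(h) > min(h)) {
      br <- seq(min(h), max(h), length.out = config$nbins + 1L)
      counts <- tabulate(findInterval(h, br, rightmost.closed = TRUE),
                         nbins = config$nbins)
      empty <- which(counts == 0)
      if (length(empty) > 0) cut <- br[empty[1]]
    } else if (length(h) > 0) cut <- max(h)
    cutree(hc, h = cut)
  }
  # deterministic ordering by smallest member index
  first <- tapply(seq_len(n), labels, min)
  ord <- order(first)
  lapply(as.integer(names(first))[ord],
         function(l) which(labels == l))
}

# connected-component labels of a logical adjacency matrix
comp_labels <- function(adj) {
  n <- nrow(adj)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Build the mapper graph of a normalized visit table
#'
#' The mapper pipeline: project every visit onto the two filter features,
#' cover the filter image with overlapping boxes, pull each box back to a bin
#' of visits, cluster each bin in the full feature space, and connect two
#' clusters whenever they share a visit.  Because boxes overlap, a visit can
#' belong to several clusters; those shared memberships are exactly what
#' creates the graph's edges.
#'
#' @param table a normalized [visit_table()].
#' @param filter_names the two filter features, axis 1 first
#'   (default `c("updrs3", "age")`).
#' @param cover a [cover_spec()].
#' @param cluster a [cluster_config()].
#' @return A `mapper_graph`: list with `clusters` (each `id`, `members`,
#'   `bin_id`; ids ordered by (bin, intra-bin index)), `edges` (2-column
#'   matrix of cluster-id pairs, i < j), `point_clusters` (per-point list of
#'   containing cluster ids), `filter_names`, `cover`, `n_points`.
#' @export
build_mapper_graph <- function(table, filter_names = c("updrs3", "age"),
                               cover = cover_spec(),
                               cluster = cluster_config()) {
  stopifnot(inherits(table, "visit_table"))
  if (nrow(table$data) == 0) abort("empty table", "progmapper_config_error")
  if (!all(filter_names %in% table$feature_names))
    abort("filter features not present", "progmapper_config_error")
  if (!table$normalized)
    abort("table must be normalized before mapper", "progmapper_config_error")
  fv <- feature_matrix(table, filter_names)
  x <- feature_matrix(table)
  boxes <- build_cover(fv, cover)
  clusters <- list()
  cid <- 0L
  for (box in boxes) {
    if (length(box$members) == 0) next
    parts <- cluster_bin(x[box$members, , drop = FALSE], cluster)
    for (part in parts) {
      cid <- cid + 1L
      clusters[[cid]] <- list(id = cid, members = box$members[part],
                              bin_id = box$bin_id)
    }
  }
  m <- length(clusters)
  point_clusters <- vector("list", nrow(x))
  for (cl in clusters)
    for (pt in cl$members)
      point_clusters[[pt]] <- c(point_clusters[[pt]], cl$id)
  pair_list <- lapply(point_clusters, function(pc) {
    if (length(pc) < 2) return(NULL)
    pc <- sort(pc)
    t(utils::combn(pc, 2))
  })
  edges <- unique(do.call(rbind, c(list(matrix(integer(0), ncol = 2)),
                                   pair_list)))
  if (nrow(edges) > 0) edges <- edges[order(edges[, 1], edges[, 2]), ,
                                      drop = FALSE]
  colnames(edges) <- c("from", "to")
  structure(list(clusters = clusters, edges = edges,
                 point_clusters = point_clusters,
                 filter_names = filter_names, cover = cover,
                 n_points = nrow(x)),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d cluster(s), %d edge(s) over %d points; filter (%s)\n",
              length(x$clusters), nrow(x$edges), x$n_points,
              paste(x$filter_names, collapse = ", ")))
  invisible(x)
}

#' Number of clusters of a mapper graph
#' @param graph a `mapper_graph`.
#' @return integer.
#' @export
n_clusters <- function(graph) length(graph$clusters)
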