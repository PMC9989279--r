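# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use explicit loops and no package internals, so
# they stay independent of the implementation paths they check.

tiny_table <- function() {
  visit_table(
    data.frame(
      patient_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
      year = c(0L, 1L, 2L, 0L, 2L, 0L),
      med_type = c(1L, 1L, 1L, 0L, 0L, 5L),
      updrs3 = c(10, 14, 18, 30, 36, 50),
      age = c(60, 61, 62, 55, 57, 70)),
    feature_names = c("updrs3", "age"))
}

# a mapper_graph hand-built from an explicit cluster list (for oracle tests)
make_test_graph <- function(clusters, n_points) {
  cl <- lapply(seq_along(clusters), function(i)
    list(id = i, members = sort(unique(clusters[[i]])), bin_id = i))
  point_clusters <- vector("list", n_points)
  for (c_ in cl)
    for (p_ in c_$members)
      point_clusters[[p_]] <- c(point_clusters[[p_]], c_$id)
  edges <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  for (i in seq_along(cl)) for (j in seq_along(cl)) {
    if (i < j && length(intersect(cl[[i]]$members, cl[[j]]$members)) > 0)
      edges <- rbind(edges, c(i, j))
  }
  structure(list(clusters = cl, edges = edges,
                 point_clusters = point_clusters,
                 filter_names = c("updrs3", "age"),
                 cover = cover_spec(1, 1, 0), n_points = n_points),
            class = "mapper_graph")
}

# random overlapping-cluster instance for the Markov / prediction oracles
random_instance <- function(n_max = 50, m_max = 10, n_pairs_max = 40,
                            dims = 3) {
  n <- sample(5:n_max, 1)
  m <- sample(2:m_max, 1)
  clusters <- vector("list", m)
  # every point in >= 1 cluster; clusters nonempty
  base <- sample.int(m, n, replace = TRUE)
  for (i in seq_len(m)) {
    mem <- which(base == i)
    extra <- which(runif(n) < 0.2)
    mem <- sort(unique(c(mem, extra)))
    if (length(mem) == 0) mem <- sample.int(n, 1)
    clusters[[i]] <- mem
  }
  k <- sample(0:n_pairs_max, 1)
  pairs <- cbind(sample.int(n, k, replace = TRUE),
                 sample.int(n, k, replace = TRUE))
  list(n = n, m = m, clusters = clusters,
       pairs = pair_set(sample(0:7, 1), pairs),
       scores = runif(n),
       cloud = matrix(runif(n * dims), nrow = n))
}

# ---- oracle: Markov matrix from first principles --------------------------
brute_transition <- function(clusters, pairs, scores, n_points) {
  m <- length(clusters)
  counts <- matrix(0, m, m)
  pr <- pairs$pairs
  if (nrow(pr) > 0) {
    for (r in seq_len(nrow(pr))) {
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (pr[r, 1] %in% clusters[[i]] && pr[r, 2] %in% clusters[[j]])
          counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  M <- matrix(0, m, m)
  for (i in seq_len(m)) {
    tot <- sum(counts[i, ])
    if (tot > 0) M[i, ] <- counts[i, ] / tot
    else M[i, i] <- 1
  }
  E <- numeric(m)
  for (j in seq_len(m)) E[j] <- mean(scores[clusters[[j]]])
  list(counts = counts, M = M, E = E,
       live = vapply(seq_len(m), function(i) sum(counts[i, ]) > 0, logical(1)))
}

# ---- oracle: kernel prediction from first principles ----------------------
brute_predict <- function(x, cloud, clusters, M, E, live, mu, sigma,
                          exclude = NULL) {
  n <- nrow(cloud)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(sum((cloud[i, ] - x)^2))
  cand <- setdiff(seq_len(n), exclude)
  cand <- cand[order(d[cand], cand)]
  nb <- cand[seq_len(mu)]
  w <- exp(-d[nb]^2 / sigma^2)
  cst <- 1 / sum(w)
  m <- length(clusters)
  v <- numeric(m)
  for (k in seq_along(nb)) {
    holds <- which(vapply(clusters, function(cl) nb[k] %in% cl, logical(1)))
    if (length(holds) == 0) next
    for (i in holds) v[i] <- v[i] + cst * w[k] / length(holds)
  }
  v[!live] <- 0
  if (sum(v) <= 0) return(NA_real_)
  v <- v / sum(v)
  vdag <- numeric(m)
  for (j in seq_len(m)) for (i in seq_len(m)) vdag[j] <- vdag[j] + v[i] * M[i, j]
  sum(vdag * E)
}
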