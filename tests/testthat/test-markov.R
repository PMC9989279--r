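test_that("arrow counting respects overlapping memberships", {
  g <- make_test_graph(list(c(1, 2), c(2), c(3)), n_points = 4)
  # a=1 in C1 only, b=3 in C3 only
  cnt <- count_arrows(g, pair_set(0, cbind(1, 3)))
  expect_equal(cnt[1, 3], 1L)
  expect_equal(sum(cnt), 1L)

  # a=2 in C1 and C2, b=3 in C3 -> one count from each source cluster
  cnt2 <- count_arrows(g, pair_set(0, cbind(2, 3)))
  expect_equal(cnt2[1, 3], 1L)
  expect_equal(cnt2[2, 3], 1L)
  expect_equal(sum(cnt2), 2L)

  # empty pair set -> zero matrix
  cnt3 <- count_arrows(g, pair_set(0, matrix(integer(0), ncol = 2)))
  expect_true(all(cnt3 == 0L))

  # endpoint in no cluster -> pair skipped with a message
  expect_message(cnt4 <- count_arrows(g, pair_set(0, cbind(4, 3))),
                 "skipped")
  expect_true(all(cnt4 == 0L))
})

test_that("transition model reproduces the hand-counted example", {
  # clusters C1 = {1, 2, 3}, C2 = {4}; pairs (1->2), (3->4):
  # row 1 counts [1, 1] -> [0.5, 0.5]; C2 is dead -> identity row
  g <- make_test_graph(list(c(1, 2, 3), c(4)), n_points = 4)
  scores <- c(0.1, 0.2, 0.3, 0.8)
  model <- build_transition_model(g, pair_set(3, cbind(c(1, 3), c(2, 4))),
                                  scores)
  expect_equal(model$M[1, ], c(0.5, 0.5))
  expect_equal(model$M[2, ], c(0, 1))
  expect_false(model$live[2])
  expect_equal(model$E, c(0.2, 0.8))

  # all pairs stay inside their own cluster -> identity matrix
  g2 <- make_test_graph(list(c(1, 2), c(3, 4)), n_points = 4)
  model2 <- build_transition_model(
    g2, pair_set(0, cbind(c(1, 3), c(2, 4))), scores)
  expect_equal(model2$M, diag(2))
})

test_that("transition models match the brute-force oracle on random instances", {
  set.seed(30)
  for (trial in 1:60) {
    inst <- random_instance()
    g <- make_test_graph(inst$clusters, inst$n)
    model <- suppressMessages(
      build_transition_model(g, inst$pairs, inst$scores))
    oracle <- brute_transition(inst$clusters, inst$pairs, inst$scores, inst$n)
    expect_equal(model$M, oracle$M, tolerance = 1e-12)
    expect_equal(unname(model$counts), oracle$counts, ignore_attr = TRUE,
                 tolerance = 0)
    expect_equal(model$E, oracle$E, tolerance = 1e-12)
    expect_equal(model$live, oracle$live)
    expect_equal(rowSums(model$M), rep(1, inst$m), tolerance = 1e-9)
  }
})

test_that("expected growth evaluates the formula and handles edge cases", {
  # identity chain -> zero growth everywhere
  g <- make_test_graph(list(c(1, 2), c(3, 4)), n_points = 4)
  scores <- c(0.1, 0.3, 0.3, 0.5)
  model <- build_transition_model(g, pair_set(0, cbind(c(1, 3), c(2, 4))),
                                  scores)
  expect_equal(model$M, diag(2))
  gr <- expected_growth(model, c(3, 1))
  expect_equal(gr$delta_j, c(0, 0))
  expect_equal(gr$delta, 0)

  # 2 clusters, E = (0.2, 0.4), row 1 = (0, 1), all mass in cluster 1
  model2 <- model
  model2$M <- rbind(c(0, 1), c(0, 1))
  model2$E <- c(0.2, 0.4)
  gr2 <- expected_growth(model2, c(5, 0))
  expect_equal(gr2$delta, 0.2)

  expect_error(expected_growth(model, c(0, 0)),
               class = "progmapper_no_visits_error")
  expect_error(expected_growth(model, c(1, 1, 1)),
               class = "progmapper_config_error")
})

test_that("expected growth is equivariant under cluster relabeling", {
  set.seed(31)
  for (trial in 1:20) {
    inst <- random_instance()
    if (nrow(inst$pairs$pairs) == 0) next
    g <- make_test_graph(inst$clusters, inst$n)
    model <- suppressMessages(
      build_transition_model(g, inst$pairs, inst$scores))
    d <- vapply(inst$clusters, length, numeric(1))
    gr <- expected_growth(model, d)

    perm <- sample(inst$m)
    g2 <- make_test_graph(inst$clusters[perm], inst$n)
    model2 <- suppressMessages(
      build_transition_model(g2, inst$pairs, inst$scores))
    gr2 <- expected_growth(model2, d[perm])
    expect_equal(gr2$delta, gr$delta, tolerance = 1e-12)
    expect_equal(gr2$delta_j, gr$delta_j[perm], tolerance = 1e-12)
  }
})

test_that("un-biased effect is zero on self and positive for a drifting chain", {
  g <- make_test_graph(list(c(1, 2), c(3, 4)), n_points = 4)
  scores <- c(0.1, 0.3, 0.3, 0.5)
  m0 <- build_transition_model(g, pair_set(0, cbind(c(1, 3), c(2, 4))),
                               scores)
  self <- unbiased_effect(m0, m0, c(0.5, 0.5))
  expect_equal(self$effect, 0)

  # un-medicated chain drifts upward (row (0,1)); medicated chain is identity
  drift0 <- m0
  drift0$M <- rbind(c(0, 1), c(0, 1))
  drift0$E <- c(0.2, 0.6)
  ident <- m0
  ident$M <- diag(2)
  ident$E <- c(0.2, 0.6)
  ub <- unbiased_effect(ident, drift0, c(1, 0))
  expect_equal(ub$delta, 0)
  expect_equal(ub$delta_prime, 0.4)
  expect_equal(ub$effect, 0.4)

  bad <- build_transition_model(
    make_test_graph(list(c(1, 2), c(3), c(4)), 4),
    pair_set(0, cbind(1, 2)), scores)
  expect_error(unbiased_effect(m0, bad, c(1, 0)),
               class = "progmapper_config_error")
})

test_that("per-cluster type counts count visits, optionally patients", {
  tab <- tiny_table()
  g <- make_test_graph(list(c(1, 2, 4), c(4, 5, 6)), n_points = 6)
  d <- cluster_type_counts(g, tab, 1)   # P1 visits are rows 1:3, type 1
  expect_equal(d, c(2, 0))
  d0 <- cluster_type_counts(g, tab, 0)  # P2 rows 4:5
  expect_equal(d0, c(1, 2))
  dp <- cluster_type_counts(g, tab, 0, per_patient = TRUE)
  expect_equal(dp, c(1, 1))
})

test_that("growth table reports normalized and de-normalized growth per type", {
  tab <- suppressWarnings(
    generate_cohort(cohort_spec(n_patients = 120, n_years = 3, seed = 32)))
  g <- build_mapper_graph(tab, cover = cover_spec(20, 1, 0.1))
  ps <- build_pair_sets(tab)
  gt <- growth_table(tab, g, ps)
  expect_true(all(gt$med_type %in% 0:7))
  expect_equal(gt$delta_abs, gt$delta * 80)
  expect_true(all(is.na(gt$delta_prime[gt$med_type == 0])))
  expect_true(all(is.finite(gt$delta)))
})
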