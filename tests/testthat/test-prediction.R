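test_that("initial vector follows the kernel rule on hand cases", {
  # mu = 1: all mass on the unique cluster of the nearest point
  g <- make_test_graph(list(c(1, 2), c(3, 4)), n_points = 4)
  cloud <- rbind(c(0, 0), c(0.1, 0), c(1, 1), c(1, 0.9))
  scores <- c(0.1, 0.2, 0.7, 0.8)
  model <- build_transition_model(
    g, pair_set(0, cbind(c(1, 3), c(2, 4))), scores)
  iv <- initial_vector(c(0, 0.01), cloud, g, model, kernel_config(1, 0.1))
  expect_equal(iv$v, c(1, 0))

  # mu = 2, equidistant neighbours in different live clusters -> (0.5, 0.5)
  cloud2 <- rbind(c(-1, 0), c(1, 0), c(5, 5), c(6, 6))
  g2 <- make_test_graph(list(c(1), c(2), c(3, 4)), n_points = 4)
  model2 <- build_transition_model(
    g2, pair_set(0, cbind(c(1, 2), c(2, 1))), scores)
  iv2 <- initial_vector(c(0, 0), cloud2, g2, model2, kernel_config(2, 1))
  expect_equal(iv2$v, c(0.5, 0.5, 0))
  expect_equal(sum(iv2$v), 1)

  # multiplicity: one neighbour in two live clusters, the other only in a
  # dead cluster -> after zeroing the dead mass, equal split remains
  g3 <- make_test_graph(list(c(1), c(1), c(2)), n_points = 2)
  cloud3 <- rbind(c(-1, 0), c(1, 0))
  model3 <- build_transition_model(
    g3, pair_set(0, cbind(1, 1)), c(0.2, 0.9))  # C3 (point 2) is dead
  iv3 <- initial_vector(c(0, 0), cloud3, g3, model3, kernel_config(2, 1))
  expect_equal(iv3$v, c(0.5, 0.5, 0))

  # all mass in dead clusters -> classed no-prediction error
  model4 <- model3
  model4$live <- c(FALSE, FALSE, TRUE)
  expect_error(
    initial_vector(c(-1, 0.01), cloud3, g3, model4, kernel_config(1, 1)),
    class = "progmapper_no_prediction_error")

  # mu larger than the available cloud -> config error
  expect_error(
    initial_vector(c(0, 0), cloud3, g3, model3, kernel_config(5, 1)),
    class = "progmapper_config_error")
})

test_that("predicted score is the chain-propagated expectation", {
  g <- make_test_graph(list(c(1, 2), c(3, 4)), n_points = 4)
  cloud <- rbind(c(0, 0), c(0.1, 0), c(1, 1), c(1, 0.9))
  scores <- c(0.1, 0.2, 0.7, 0.8)
  model <- build_transition_model(
    g, pair_set(0, cbind(c(1, 3), c(2, 4))), scores)
  # identity chain: prediction equals the cluster expectation
  expect_equal(model$M, diag(2))
  expect_equal(predict_score(c(0, 0.01), cloud, g, model,
                             kernel_config(1, 0.1)),
               model$E[1])

  # v = (1, 0) with row 1 = (0, 1), E = (0.2, 0.6) -> 0.6
  model2 <- model
  model2$M <- rbind(c(0, 1), c(0, 1))
  model2$E <- c(0.2, 0.6)
  expect_equal(predict_score(c(0, 0.01), cloud, g, model2,
                             kernel_config(1, 0.1)),
               0.6)
})

test_that("prediction matches the explicit-loop oracle and stays in [min E, max E]", {
  set.seed(40)
  for (trial in 1:60) {
    inst <- random_instance(n_max = 40, m_max = 8)
    if (nrow(inst$pairs$pairs) < 1) next
    g <- make_test_graph(inst$clusters, inst$n)
    model <- suppressMessages(
      build_transition_model(g, inst$pairs, inst$scores))
    if (!any(model$live)) next
    x <- runif(ncol(inst$cloud))
    mu <- sample(1:min(8, inst$n - 1), 1)
    sigma <- runif(1, 0.05, 0.5)
    cfg <- kernel_config(mu, sigma)
    got <- tryCatch(
      predict_score(x, inst$cloud, g, model, cfg),
      progmapper_no_prediction_error = function(e) NA_real_)
    want <- brute_predict(x, inst$cloud, inst$clusters, model$M, model$E,
                          model$live, mu, sigma)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
      expect_gte(got, min(model$E) - 1e-12)
      expect_lte(got, max(model$E) + 1e-12)
    }
  }
})

test_that("leave-one-out evaluation computes the statistics it reports", {
  tab <- suppressWarnings(generate_cohort(
    cohort_spec(n_patients = 80, n_years = 3, noise_sd = 0.01, seed = 41)))
  ps <- build_pair_sets(tab)
  t_big <- names(which.max(vapply(ps, function(p) nrow(p$pairs), numeric(1))))
  pairs <- ps[[t_big]]
  scores <- tab$data$updrs3
  cloud <- feature_matrix(tab)
  g <- build_mapper_graph(tab, cover = cover_spec(10, 2, 0.2))
  model <- build_transition_model(g, pairs, scores)
  rep <- loo_evaluate(pairs, cloud, g, model, scores = scores)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n + rep$n_failed, nrow(pairs$pairs))
  expect_gte(rep$max_error, rep$mae_abs)
  expect_gte(rep$mse, 0)
  expect_true(rep$hit_in_pct >= 0 && rep$hit_in_pct <= 100)
  # reported statistics agree with their definitions on the per-pair table
  err <- rep$predictions$predicted - rep$predictions$actual
  expect_equal(rep$mean_error, mean(err))
  expect_equal(rep$mae_abs, mean(abs(err)))
  expect_equal(rep$mse, mean(err^2))
  act <- rep$predictions$actual
  expect_equal(rep$r2, 1 - sum(err^2) / sum((act - mean(act))^2))
  expect_equal(rep$hit_in_pct, 100 * mean(abs(err) <= rep$tolerance))

  expect_error(
    loo_evaluate(pair_set(0, cbind(1, 2)), cloud, g, model, scores = scores),
    class = "progmapper_config_error")
})

test_that("full-rebuild leave-one-out runs on a small cloud", {
  tab <- suppressWarnings(generate_cohort(
    cohort_spec(n_patients = 40, n_years = 3, noise_sd = 0.01, seed = 45)))
  ps <- build_pair_sets(tab)
  t_big <- names(which.max(vapply(ps, function(p) nrow(p$pairs), numeric(1))))
  pairs <- ps[[t_big]]
  scores <- tab$data$updrs3
  cloud <- feature_matrix(tab)
  cov <- cover_spec(6, 1, 0.2)
  g <- build_mapper_graph(tab, cover = cov)
  model <- build_transition_model(g, pairs, scores)
  rep <- suppressMessages(loo_evaluate(
    pairs, cloud, g, model, scores = scores, mode = "rebuild",
    table = tab, cover = cov, cfg = kernel_config(5, 0.0378)))
  expect_true(is.finite(rep$mse))
  expect_equal(rep$n + rep$n_failed, nrow(pairs$pairs))
})

test_that("a constant predictor has R2 = 0 by construction of the statistic", {
  # degenerate world: a single live cluster, so every prediction is E[1] --
  # the mean-of-cluster constant predictor
  n <- 12
  cloud <- matrix(runif(2 * n), ncol = 2)
  g <- make_test_graph(list(seq_len(n)), n_points = n)
  pairs <- pair_set(0, cbind(1:4, 2:5))
  scores <- seq(0, 1, length.out = n)
  model <- build_transition_model(g, pairs, scores)
  rep <- loo_evaluate(pairs, cloud, g, model, scores = scores,
                      mode = "neighbors", cfg = kernel_config(3, 0.5))
  expect_equal(rep$predictions$predicted, rep(model$E[1], 4))
  y <- scores[2:5]
  expect_equal(rep$r2, 1 - sum((model$E[1] - y)^2) / sum((y - mean(y))^2))
})

test_that("the Markov step adds drift beyond a no-change predictor", {
  tab <- suppressWarnings(generate_cohort(cohort_spec(
    n_patients = 150, n_years = 4, noise_sd = 0.005,
    drift = setNames(rep(0.03, 8), 0:7), seed = 42)))
  ps <- build_pair_sets(tab)
  t_big <- names(which.max(vapply(ps, function(p) nrow(p$pairs), numeric(1))))
  pairs <- ps[[t_big]]
  scores <- tab$data$updrs3
  cloud <- feature_matrix(tab)
  g <- build_mapper_graph(tab, cover = cover_spec(40, 1, 0.1))
  model <- build_transition_model(g, pairs, scores)
  rep <- loo_evaluate(pairs, cloud, g, model, scores = scores)
  # naive "no change": predict this year's score for next year; with strictly
  # increasing scores it lags (negative mean signed error)
  naive_err <- mean(scores[pairs$pairs[, 1]] - scores[pairs$pairs[, 2]])
  expect_lt(naive_err, 0)
  expect_lt(abs(rep$mean_error), abs(naive_err))
})

test_that("excluding the held-out point matters (leakage guard)", {
  tab <- suppressWarnings(generate_cohort(
    cohort_spec(n_patients = 100, n_years = 3, seed = 43)))
  ps <- build_pair_sets(tab)
  t_big <- names(which.max(vapply(ps, function(p) nrow(p$pairs), numeric(1))))
  pairs <- ps[[t_big]]
  scores <- tab$data$updrs3
  cloud <- feature_matrix(tab)
  g <- build_mapper_graph(tab, cover = cover_spec(20, 2, 0.1))
  model <- build_transition_model(g, pairs, scores)
  loo <- loo_evaluate(pairs, cloud, g, model, scores = scores)
  # no-exclusion run: x0 is its own nearest neighbour
  leak_err <- vapply(seq_len(nrow(pairs$pairs)), function(r) {
    p <- tryCatch(
      predict_score(cloud[pairs$pairs[r, 1], ], cloud, g, model),
      progmapper_no_prediction_error = function(e) NA_real_)
    abs(p - scores[pairs$pairs[r, 2]])
  }, numeric(1))
  expect_lte(mean(leak_err, na.rm = TRUE), loo$mae_abs + 1e-9)
})

test_that("cover-parameter tuning ranks the grid and survives degenerate specs", {
  tab <- suppressWarnings(generate_cohort(
    cohort_spec(n_patients = 80, n_years = 3, noise_sd = 0.01, seed = 44)))
  ps <- build_pair_sets(tab)
  t_big <- names(which.max(vapply(ps, function(p) nrow(p$pairs), numeric(1))))
  pairs <- ps[[t_big]]

  single <- tune_cover_parameters(list(cover_spec(10, 2, 0.1)), tab, pairs)
  expect_equal(single$best$n1, 10)
  expect_equal(nrow(single$results), 1)

  grid <- list(cover_spec(20, 40, 0.05), cover_spec(20, 40, 0.3),
               cover_spec(1, 1, 0))
  tuned <- suppressMessages(tune_cover_parameters(grid, tab, pairs))
  expect_equal(nrow(tuned$results), 3)
  expect_true(all(is.finite(tuned$results$hit_in_pct)))
  expect_true(!is.unsorted(-tuned$results$hit_in_pct))
  expect_error(tune_cover_parameters(list(), tab, pairs),
               class = "progmapper_config_error")
})
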