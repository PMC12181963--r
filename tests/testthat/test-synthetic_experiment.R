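test_that("make_ground_truth_map builds the documented families", {
  tent <- tent_map()
  expect_equal(nrow(tent$branches), 2)
  expect_equal(tent$branches$slope, c(2, -2))

  skew <- make_ground_truth_map("skew_tent", p = unit_partition(), peak = 0.25)
  expect_equal(skew$branches$slope, c(4, -4 / 3))

  p8 <- partition(0, 4, 8)
  m1 <- make_ground_truth_map("random_semi_markov", p = p8, seed = 10)
  m2 <- make_ground_truth_map("random_semi_markov", p = p8, seed = 10)
  expect_identical(m1$branches, m2$branches)

  expect_error(make_ground_truth_map("logistic"), class = "pwlmap_validation")
})

test_that("simulate_sorting_experiment gates day 0 and records days 0..days", {
  map <- make_ground_truth_map("random_semi_markov", p = partition(0, 4, 8), seed = 3)
  b <- simulate_sorting_experiment(map, n_cells = 2000, days = 5, seed = 3)
  expect_named(b$series, c("negative", "low", "medium", "high"))
  for (gi in seq_along(b$gates)) {
    s <- b$series[[gi]]
    expect_length(s$densities, 6)
    g <- b$gates[[gi]]
    f0 <- s$densities[[1]]
    p <- f0$partition
    outside <- p$edges[-1] <= g$lo | p$edges[-length(p$edges)] >= g$hi
    expect_true(all(f0$values[outside] == 0))
  }
  # determinism per seed
  b2 <- simulate_sorting_experiment(map, n_cells = 2000, days = 5, seed = 3)
  expect_identical(b$series$low$densities[[6]]$values,
                   b2$series$low$densities[[6]]$values)
})

test_that("a gate capturing no burned-in mass raises an empty-gate error", {
  # map pushing everything into the top half of the domain
  p <- partition(0, 4, 8)
  up <- pwl_map(p, data.frame(x_lo = 0, x_hi = 4, slope = 0.5, intercept = 2))
  expect_error(
    simulate_sorting_experiment(up, gates = list(sorting_gate("empty", 0, 0.5)),
                                n_cells = 2000, days = 2, seed = 1),
    class = "pwlmap_empty_gate")
})

test_that("event tables carry log-normal measurement noise on the linear scale", {
  map <- tent_map(partition(0, 1, 4))
  b <- simulate_sorting_experiment(map, gates = default_gates(map$partition, c("lo", "hi"))[1],
                                   n_cells = 1000, days = 2, seed = 5,
                                   event_tables = TRUE, measurement_sigma = 0.05)
  raw <- b$event_tables$lo
  expect_length(raw, 3)
  expect_true(all(raw[[1]] > 0))
  # day-0 measurements scatter around the gate interval [0, 0.5) in log10
  expect_gt(mean(log10(raw[[1]])), -0.2)
  expect_lt(mean(log10(raw[[1]])), 0.7)
})

test_that("gated fractions revert toward the invariant density", {
  map <- make_ground_truth_map("random_semi_markov", p = partition(0, 4, 8), seed = 8)
  finv <- invariant_density(transfer_matrix_of_map(map), tol = 1e-12)
  b <- simulate_sorting_experiment(map, n_cells = 10000, days = 30, seed = 8)
  for (s in b$series) {
    d0 <- l1_distance(s$densities[[1]], finv)
    d30 <- l1_distance(s$densities[[31]], finv)
    expect_lt(d30, d0)
  }
})

test_that("recovery_report scores self-comparison at zero and validates partitions", {
  map <- make_ground_truth_map("random_semi_markov", p = partition(0, 4, 8), seed = 14)
  b <- simulate_sorting_experiment(map, n_cells = 2000, days = 3, seed = 14)
  Q_true <- transfer_matrix_of_map(map)
  self <- structure(list(map = map, Q_hat = Q_true, residual = 0, n_pairs = 1L,
                         per_pair_l1 = 0, sigma_hat = NA_real_),
                    class = "pwl_inference_result")
  rep <- recovery_report(b, self)
  expect_equal(rep$q_max_err, 0)
  expect_equal(rep$q_frobenius_err, 0)
  expect_lt(rep$invariant_l1_err, 1e-8)
  expect_equal(rep$n_fixed_matched, rep$n_fixed_true)
  expect_true(is.na(rep$sigma_err))

  other <- make_ground_truth_map("random_semi_markov", p = partition(0, 4, 4), seed = 2)
  wrong <- structure(list(map = other, Q_hat = transfer_matrix_of_map(other),
                          residual = 0, n_pairs = 1L, per_pair_l1 = 0,
                          sigma_hat = NA_real_),
                     class = "pwl_inference_result")
  expect_error(recovery_report(b, wrong), class = "pwlmap_incompatible")
})

test_that("noise-free exact-coverage inference scores near-zero Frobenius error", {
  p <- partition(0, 4, 8)
  map <- make_ground_truth_map("random_semi_markov", p = p, seed = 15)
  Qm <- transfer_matrix_of_map(map)
  series <- lapply(seq_len(p$n), function(i)
    exact_series(paste0("ind", i), indicator_densities(p)[[i]], Qm, 1))
  fit <- suppressMessages(infer_map_from_series(series, ridge = 0))
  bundle <- structure(list(truth_map = map, truth_sigma = 0, series = series,
                           gates = NULL, event_tables = NULL),
                      class = "pwl_experiment_bundle")
  rep <- recovery_report(bundle, fit)
  expect_lt(rep$q_frobenius_err, 1e-6)
})
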