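test_that("estimate_transfer_matrix recovers Q exactly from spanning pairs", {
  p <- partition(0, 4, 8)
  Q_true <- random_stochastic(8, 31)
  Qm <- transfer_matrix(p, Q_true)
  pairs <- lapply(indicator_densities(p),
                  function(f) list(f, evolve_density(Qm, f)))
  Q_hat <- estimate_transfer_matrix(pairs, ridge = 0)
  expect_lt(max(abs(Q_hat$Q - Q_true)), 1e-8)
})

test_that("estimate_transfer_matrix resolves underdetermined fits to uniform", {
  p <- partition(0, 4, 4)
  u <- uniform_density(p)
  Q <- estimate_transfer_matrix(list(list(u, u)), ridge = 1e-4)
  expect_equal(Q$Q, matrix(0.25, 4, 4), tolerance = 1e-8)
})

test_that("estimate_transfer_matrix validates inputs", {
  p <- partition(0, 4, 4)
  u <- uniform_density(p)
  expect_error(estimate_transfer_matrix(list()), class = "pwlmap_empty_input")
  expect_error(estimate_transfer_matrix(
    list(list(u, uniform_density(partition(0, 4, 8))))),
    class = "pwlmap_incompatible")
  expect_error(estimate_transfer_matrix(list(list(u, u)), ridge = -1),
               class = "pwlmap_validation")
  # rank-deficient system at ridge 0
  expect_error(estimate_transfer_matrix(list(list(u, u)), ridge = 0),
               class = "pwlmap_numerical")
})

test_that("estimate_transfer_matrix output always passes matrix invariants", {
  p <- partition(0, 4, 6)
  for (s in 1:8) {
    set.seed(800 + s)
    k <- sample(2:8, 1)
    pairs <- lapply(seq_len(k), function(i)
      list(random_density(p, 900 + 10 * s + i), random_density(p, 950 + 10 * s + i)))
    Q <- suppressMessages(estimate_transfer_matrix(pairs))$Q
    expect_true(all(Q >= 0) && all(Q <= 1))
    expect_true(all(abs(rowSums(Q) - 1) <= 1e-9))
  }
})

test_that("construct_semi_markov_map builds the canonical realisation", {
  # identity matrix -> cell-wise identity map
  p <- partition(0, 4, 4)
  m <- construct_semi_markov_map(transfer_matrix(p, diag(4)))
  expect_equal(nrow(m$branches), 4)
  expect_equal(m$branches$slope, rep(1, 4))
  expect_equal(m$branches$intercept, rep(0, 4))

  # 2-cell uniform partition, all-half matrix: 4 branches of slope 2 on
  # quarter-width sub-intervals
  p2 <- unit_partition()
  m2 <- construct_semi_markov_map(transfer_matrix(p2, matrix(0.5, 2, 2)))
  expect_equal(nrow(m2$branches), 4)
  expect_equal(m2$branches$slope, rep(2, 4))
  expect_equal(m2$branches$x_hi - m2$branches$x_lo, rep(0.25, 4))

  # row e_j: one branch spanning cell i onto cell j
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- 1; Q[2, 1] <- 1; Q[3, 2] <- 1; Q[4, 4] <- 1   # row 1 -> cell 3, etc.
  m3 <- construct_semi_markov_map(transfer_matrix(p, Q))
  b1 <- m3$branches[m3$branches$x_lo == 0, ]
  expect_equal(b1$x_hi, 1)
  expect_equal(b1$slope * 0 + b1$intercept, 2)   # cell 3 starts at 2
  expect_equal(b1$slope, 1)                      # equal cell widths

  expect_error(construct_semi_markov_map(matrix(1, 4, 4), p),
               class = "pwlmap_invalid_matrix")
})

test_that("round trip transfer_matrix_of_map(construct_semi_markov_map(Q)) == Q", {
  for (s in 1:20) {
    p <- partition(0, 4, 8)
    Q <- random_stochastic(8, 1000 + s)
    m <- construct_semi_markov_map(transfer_matrix(p, Q))
    expect_lt(max(abs(transfer_matrix_of_map(m)$Q - Q)), 1e-10)
  }
  # non-uniform partition
  pnu <- partition(edges = c(0, 0.3, 1.1, 2, 4))
  Q <- random_stochastic(4, 77)
  m <- construct_semi_markov_map(transfer_matrix(pnu, Q))
  expect_lt(max(abs(transfer_matrix_of_map(m)$Q - Q)), 1e-10)
})

test_that("infer_map_from_series recovers the map from exact series", {
  p <- partition(0, 4, 8)
  Q_true <- random_stochastic(8, 55)
  Qm <- transfer_matrix(p, Q_true)
  inds <- indicator_densities(p)
  # four fractions starting from two-cell gate densities, 5 days each
  starts <- lapply(1:4, function(g)
    pwc_density(p, (inds[[2 * g - 1]]$values + inds[[2 * g]]$values) / 2))
  series <- lapply(1:4, function(g)
    exact_series(c("negative", "low", "medium", "high")[g], starts[[g]], Qm, 5))
  fit <- suppressMessages(infer_map_from_series(series, ridge = 0))
  expect_lt(max(abs(fit$Q_hat$Q - Q_true)), 1e-6)
  expect_lt(fit$residual, 1e-8)
  expect_equal(fit$n_pairs, 20L)
  # round-trip contract on the result
  expect_lt(max(abs(transfer_matrix_of_map(fit$map)$Q - fit$Q_hat$Q)), 1e-10)
})

test_that("infer_map_from_series rejects day gaps and short series", {
  p <- partition(0, 4, 4)
  Q <- transfer_matrix(p, random_stochastic(4, 2))
  f <- uniform_density(p)
  gap <- density_series("x", c(0L, 2L), list(f, evolve_density(Q, f)))
  expect_error(infer_map_from_series(gap), class = "pwlmap_gap")
  short <- density_series("x", 0L, list(f))
  expect_error(infer_map_from_series(short), class = "pwlmap_empty_input")
})

test_that("more independent training pairs never hurt recovery on average", {
  p <- partition(0, 4, 8)
  Q_true <- random_stochastic(8, 123)
  n_events <- 2000
  err_at <- function(n_pairs, seed) {
    set.seed(seed)
    pairs <- lapply(seq_len(n_pairs), function(k) {
      f <- random_density(p, seed * 100 + k)
      m_next <- as.numeric(crossprod(Q_true, mass_of_test(f)))
      y <- tabulate(sample.int(8, n_events, TRUE, prob = m_next), 8) / n_events
      list(f, pwc_density(p, y / cell_widths(p)))
    })
    max(abs(suppressMessages(estimate_transfer_matrix(pairs))$Q - Q_true))
  }
  mass_of_test <- function(f) f$values * cell_widths(f$partition)
  errs <- sapply(1:20, function(r)
    sapply(c(4, 8, 16), function(np) err_at(np, 3000 + r)))
  mean_err <- rowMeans(errs)
  expect_true(all(diff(mean_err) <= 0))
})

test_that("fit_noise_sigma picks sigma 0 on noise-free data and validates the grid", {
  # sparse truth (tent map): its transfer matrix has zero entries, so a
  # spurious blur cannot be absorbed and strictly worsens the fit. (For
  # dense truths the blur is exactly absorbable and sigma is identified
  # only up to one grid step -- see the vignette.)
  p <- partition(0, 4, 8)
  Qm <- transfer_matrix_of_map(tent_map(p))
  inds <- indicator_densities(p)
  series <- lapply(1:4, function(g)
    exact_series(paste0("f", g),
                 pwc_density(p, (inds[[2 * g - 1]]$values + inds[[2 * g]]$values) / 2),
                 Qm, 4))
  fit <- suppressMessages(fit_noise_sigma(series, c(0, 0.1, 0.2)))
  expect_equal(fit$sigma_hat, 0)
  expect_true(all(diff(fit$score_by_sigma) >= 0))

  expect_error(fit_noise_sigma(series, numeric(0)), class = "pwlmap_empty_input")
  expect_error(fit_noise_sigma(series, c(-0.1, 0.1)), class = "pwlmap_validation")
})

test_that("blur_matrix is row-stochastic and nests the identity", {
  p <- partition(0, 4, 8)
  expect_equal(blur_matrix(p, 0), diag(8))
  for (sig in c(0.05, 0.2, 1)) {
    G <- blur_matrix(p, sig)
    expect_true(all(G >= 0))
    expect_equal(rowSums(G), rep(1, 8))
  }
  # heavier blur moves more mass off the diagonal
  expect_gt(mean(diag(blur_matrix(p, 0.1))), mean(diag(blur_matrix(p, 0.3))))
})
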