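test_that("apply_map evaluates branches on half-open domains", {
  p <- partition(0, 4, 4)
  ident <- pwl_map(p, data.frame(x_lo = 0, x_hi = 4, slope = 1, intercept = 0))
  expect_equal(apply_map(ident, 1.5), 1.5)

  tent <- tent_map()
  expect_equal(apply_map(tent, 0.25), 0.5)
  expect_equal(apply_map(tent, c(0, 0.5, 0.75)), c(0, 1, 0.5))

  expect_error(apply_map(ident, 4.0), class = "pwlmap_domain")
  expect_error(apply_map(tent, -0.1), class = "pwlmap_domain")
})

test_that("map validation rejects gaps, overlaps and escaping images", {
  p <- unit_partition()
  expect_error(pwl_map(p, data.frame(x_lo = c(0, 0.6), x_hi = c(0.5, 1),
                                     slope = 1, intercept = 0)),
               class = "pwlmap_invalid_map")
  expect_error(pwl_map(p, data.frame(x_lo = 0, x_hi = 1, slope = 2, intercept = 0)),
               class = "pwlmap_invalid_map")
})

test_that("transfer_matrix_of_map computes exact preimage measures", {
  # cell-wise identity -> identity matrix
  p <- partition(0, 4, 4)
  ident <- pwl_map(p, data.frame(x_lo = 0, x_hi = 4, slope = 1, intercept = 0))
  expect_equal(transfer_matrix_of_map(ident)$Q, diag(4))

  # tent map on a 2-cell partition
  expect_equal(transfer_matrix_of_map(tent_map())$Q,
               matrix(0.5, 2, 2))

  # single branch mapping cell 1 linearly onto cell 4 (plus identity elsewhere)
  m <- pwl_map(p, data.frame(x_lo = c(0, 1), x_hi = c(1, 4),
                             slope = c(1, 1), intercept = c(3, 0)))
  Q <- transfer_matrix_of_map(m)$Q
  expect_equal(Q[1, ], c(0, 0, 0, 1))
})

test_that("transfer matrix agrees with Monte-Carlo transition frequencies", {
  # the independent oracle: seed >= 1e5 uniform points per cell, push them
  # through the map, compare empirical frequencies within 3 binomial SEs
  p <- partition(0, 1, 4)
  maps <- list(make_ground_truth_map("skew_tent", p = p, peak = 0.3),
               make_ground_truth_map("random_semi_markov", p = p, seed = 3),
               make_ground_truth_map("random_semi_markov", p = p, seed = 4))
  n <- 1e5
  for (map in maps) {
    Q <- transfer_matrix_of_map(map)$Q
    set.seed(99)
    for (i in seq_len(p$n)) {
      x <- runif(n, p$edges[i], p$edges[i + 1])
      j <- cell_index_of(p, pmin(apply_map(map, x), p$hi - 1e-12))
      freq <- tabulate(j, p$n) / n
      se <- sqrt(pmax(Q[i, ] * (1 - Q[i, ]), 1e-12) / n)
      expect_true(all(abs(freq - Q[i, ]) <= 3 * se + 1e-6))
    }
  }
})

test_that("evolve_density conserves mass and fixes the documented cases", {
  p <- unit_partition()
  tentQ <- transfer_matrix_of_map(tent_map())
  u <- uniform_density(p)
  expect_equal(evolve_density(tentQ, u)$values, u$values)

  ident <- transfer_matrix(p, diag(2))
  f <- pwc_density(p, c(1.6, 0.4))
  expect_equal(evolve_density(ident, f)$values, f$values)

  p8 <- partition(0, 4, 8)
  Q8 <- transfer_matrix(p8, random_stochastic(8, 17))
  for (s in 1:10) {
    f <- random_density(p8, 400 + s)
    out <- evolve_density(Q8, f)
    expect_lt(abs(sum(out$values * cell_widths(p8)) - 1), 1e-9)
    expect_true(all(out$values >= 0))
  }
  expect_error(evolve_density(Q8, u), class = "pwlmap_incompatible")
})

test_that("evolve_density is an L1 contraction", {
  p8 <- partition(0, 4, 8)
  for (s in 1:10) {
    Q <- transfer_matrix(p8, random_stochastic(8, 500 + s))
    f <- random_density(p8, 600 + s)
    g <- random_density(p8, 700 + s)
    expect_lte(l1_distance(evolve_density(Q, f), evolve_density(Q, g)),
               l1_distance(f, g) + 1e-12)
  }
})

test_that("invariant_density converges for mixing chains and errors on cycles", {
  # doubly stochastic: uniform is returned immediately
  tentQ <- transfer_matrix_of_map(tent_map())
  expect_equal(invariant_density(tentQ)$values, c(1, 1))

  p8 <- partition(0, 4, 8)
  Q <- transfer_matrix(p8, random_stochastic(8, 21))
  f <- invariant_density(Q, tol = 1e-12)
  expect_lt(l1_distance(evolve_density(Q, f), f), 1e-12)

  # period-2 permutation: uniform start is a fixed point, perturbed start cycles
  perm <- transfer_matrix(unit_partition(), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(invariant_density(perm)$values, c(1, 1))
  bumped <- pwc_density(unit_partition(), c(1.4, 0.6))
  err <- tryCatch(invariant_density(perm, max_iter = 1000, init = bumped),
                  error = identity)
  expect_s3_class(err, "pwlmap_convergence")
  expect_gt(err$residual, 0)
})

test_that("map JSON serialisation round-trips and validates on read", {
  map <- make_ground_truth_map("random_semi_markov", p = partition(0, 4, 6), seed = 9)
  path <- tempfile(fileext = ".json")
  write_map_json(map, path)
  back <- read_map_json(path)
  expect_equal(back$branches, map$branches, tolerance = 1e-14)
  expect_equal(back$partition$edges, map$partition$edges)

  # corrupt a slope so a branch image escapes the domain
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$branches$slope[1] <- 1e6
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  expect_error(read_map_json(path), class = "pwlmap_invalid_map")
})
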