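# Shared fixtures, all built in code.

unit_partition <- function(n = 2) partition(0, 1, n)

tent_map <- function(p = unit_partition()) make_ground_truth_map("tent", p = p)

# random row-stochastic matrix with Dirichlet(1, ..., 1) rows
random_stochastic <- function(n, seed) {
  set.seed(seed)
  Q <- matrix(rexp(n * n), n, n)
  Q / rowSums(Q)
}

# the n cell-indicator densities of a partition (all mass in one cell)
indicator_densities <- function(p) {
  lapply(seq_len(p$n), function(i) {
    h <- rep(0, p$n)
    h[i] <- 1 / cell_widths(p)[i]
    pwc_density(p, h)
  })
}

random_density <- function(p, seed) {
  set.seed(seed)
  h <- rexp(p$n)
  pwc_density(p, h / sum(h * cell_widths(p)))
}

# exact (operator-level) density series: evolve f0 for `days` steps under Q
exact_series <- function(label, f0, Qm, days) {
  dens <- vector("list", days + 1)
  dens[[1]] <- f0
  for (d in seq_len(days)) dens[[d + 1]] <- evolve_density(Qm, dens[[d]])
  density_series(label, 0:days, dens)
}

write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# independent fixed-point oracle: per-branch closed-form scan of S(x) - x on
# a `step`-resolution grid, counting sign changes and exact zeros within a
# branch only (discontinuity sign flips across branch boundaries are not
# fixed points). Roots located exactly by affine interpolation.
scan_fixed_points <- function(map, step = 1e-6) {
  b <- map$branches
  roots <- numeric(0)
  for (k in seq_len(nrow(b))) {
    x <- seq(b$x_lo[k], b$x_hi[k], by = step)
    x <- x[x < b$x_hi[k]]
    # close the trailing sub-step gap so no root hides before x_hi
    x <- c(x, b$x_hi[k] - step * 1e-3)
    g <- (b$slope[k] - 1) * x + b$intercept[k]
    if (length(x) < 2) next
    s <- sign(g)
    hit <- which(s[-length(s)] * s[-1] < 0)
    for (i in hit) {
      # affine g: root by exact interpolation over the actual spacing
      roots <- c(roots, x[i] - g[i] * (x[i + 1] - x[i]) / (g[i + 1] - g[i]))
    }
    roots <- c(roots, x[s == 0])
  }
  sort(unique(roots))
}
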