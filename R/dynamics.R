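#' Fixed points of a piecewise-linear map
#'
#' Equilibria solve `S(x*) = x*`; geometrically they are intersections of
#' the map graph with the diagonal `y = x`. Because branches are affine the
#' candidates are computed in closed form per branch, `x* = intercept /
#' (1 - slope)`, and kept iff they fall in that branch's half-open domain --
#' exact, and immune to the discontinuities at branch boundaries. Branches
#' with slope 1 and intercept 0 are whole intervals of fixed points and are
#' reported separately as degenerate continua; slope 1 with non-zero
#' intercept has no fixed point.
#'
#' Numerical edge: a branch mapping exactly onto the top of the domain has
#' its diagonal crossing at the branch's open upper endpoint; float rounding
#' can place the candidate a few ulps inside. Candidates within 1e-9 of the
#' open end (relative to the domain span) are treated as boundary artifacts
#' and dropped.
#'
#' @param map a `pwl_map`.
#' @return a `pwl_fixed_points`: list with `points` (data.frame `x_star`,
#'   `branch_index`, `slope`, `stable`, `marginal`, sorted by `x_star`) and
#'   `degenerate_branches` (indices of identity branches). Stability uses
#'   the strict criterion `|slope| < 1`; `|slope| == 1` is flagged marginal.
#' @export
find_fixed_points <- function(map) {
  b <- map$branches
  edge_tol <- 1e-9 * (map$partition$hi - map$partition$lo)
  xs <- numeric(0); bi <- integer(0); sl <- numeric(0)
  degen <- integer(0)
  for (k in seq_len(nrow(b))) {
    s <- b$slope[k]; c0 <- b$intercept[k]
    if (s == 1) {
      if (c0 == 0) degen <- c(degen, k)
      next
    }
    x_star <- c0 / (1 - s)
    if (x_star >= b$x_lo[k] && x_star < b$x_hi[k] - edge_tol) {
      xs <- c(xs, x_star); bi <- c(bi, k); sl <- c(sl, s)
    }
  }
  ord <- order(xs)
  pts <- data.frame(x_star = xs[ord], branch_index = bi[ord], slope = sl[ord],
                    stable = abs(sl[ord]) < 1, marginal = abs(sl[ord]) == 1)
  structure(list(points = pts, degenerate_branches = degen),
            class = "pwl_fixed_points")
}

#' @export
print.pwl_fixed_points <- function(x, ...) {
  if (length(x$degenerate_branches))
    cat(sprintf("Degenerate continua of fixed points on branch(es): %s\n",
                paste(x$degenerate_branches, collapse = ", ")))
  if (nrow(x$points) == 0) cat("No isolated fixed points.\n")
  else print(format(x$points, digits = 6))
  invisible(x)
}

#' Lyapunov exponent of a map under a density
#'
#' The expected log stretching rate `integral f(x) ln|S'(x)| dx`, computed
#' exactly from branch geometry: within each cell the integrand is piecewise
#' constant, so the within-cell average of `ln|slope|` is the
#' branch-sub-interval-width-weighted mean. Evaluated at the invariant
#' density this is the Lyapunov exponent of the attractor; positive values
#' indicate expanding-on-average (chaotic) dynamics.
#'
#' @param map a `pwl_map`.
#' @param f a `pwl_density` on the map's partition.
#' @return scalar Lyapunov exponent (nats per day).
#' @export
lyapunov_exponent <- function(map, f) {
  check_same_partition(map$partition, f$partition)
  p <- map$partition
  b <- map$branches
  zero <- b$slope == 0
  if (any(zero)) {
    # zero slope on positive f-mass => log-derivative diverges
    for (k in which(zero)) {
      i1 <- cell_index_of(p, b$x_lo[k])
      i2 <- cell_index_of(p, b$x_hi[k] - 1e-15)
      if (any(f$values[i1:i2] > 0))
        pwl_stop("divergence",
                 "a zero-slope branch carries positive density mass; ln|S'| diverges")
    }
  }
  e <- p$edges
  total <- 0
  for (k in seq_len(nrow(b))) {
    if (b$slope[k] == 0) next
    i_first <- max(1L, findInterval(b$x_lo[k], e))
    i_last <- min(p$n, findInterval(b$x_hi[k], e, left.open = TRUE))
    for (i in i_first:i_last) {
      ov <- min(b$x_hi[k], e[i + 1]) - max(b$x_lo[k], e[i])
      if (ov > 0) total <- total + f$values[i] * ov * log(abs(b$slope[k]))
    }
  }
  total
}

#' Trajectory estimate of the Lyapunov exponent
#'
#' Independent check on [lyapunov_exponent()]: iterates a single orbit for
#' `n_steps` and averages `ln|S'(x_t)|` along it (compiled loop; the orbit
#' is inherently sequential).
#'
#' @param map a `pwl_map`.
#' @param x0 interior starting point.
#' @param n_steps orbit length (default 1e6).
#' @return scalar estimate.
#' @export
lyapunov_trajectory <- function(map, x0, n_steps = 1e6) {
  b <- map$branches
  pwl_assert(x0 >= map$partition$lo && x0 < map$partition$hi, "domain",
             "`x0` outside the map domain")
  orbit_mean_log_slope(b$x_lo, b$slope, b$intercept,
                       map$partition$lo, map$partition$hi,
                       x0, as.integer(n_steps))
}

# Build the perturbed map S_beta for the built-in one-parameter families.
perturb_map <- function(map, family = c("pull_to_identity", "additive_shift"), beta) {
  pwl_assert(family[1] %in% c("pull_to_identity", "additive_shift"),
             "validation", sprintf("unknown perturbation family '%s'", family[1]))
  family <- match.arg(family)
  p <- map$partition
  b <- map$branches
  if (family == "pull_to_identity") {
    pwl_assert(beta >= 0 && beta <= 1, "validation",
               "pull_to_identity requires beta in [0, 1]")
    # S_b(x) = (1-b) S(x) + b x : still affine per branch, images are convex
    # combinations of in-domain values, hence in-domain
    pwl_map(p, data.frame(x_lo = b$x_lo, x_hi = b$x_hi,
                          slope = (1 - beta) * b$slope + beta,
                          intercept = (1 - beta) * b$intercept))
  } else {
    # S_b(x) = clip(S(x) + beta): shifted branches are split where the image
    # crosses a domain bound; saturated parts become slope-0 branches
    rows <- list()
    for (k in seq_len(nrow(b))) {
      s <- b$slope[k]; c0 <- b$intercept[k] + beta
      seg <- split_clipped_branch(b$x_lo[k], b$x_hi[k], s, c0, p$lo, p$hi)
      rows[[k]] <- seg
    }
    pwl_map(p, do.call(rbind, rows))
  }
}

# Split an affine branch y = s x + c on [x_lo, x_hi) so that the clipped map
# clip(y, lo, hi) is represented exactly: in-range part keeps (s, c),
# saturated parts become constant branches at lo or hi.
split_clipped_branch <- function(x_lo, x_hi, s, c0, lo, hi) {
  if (s == 0) {
    y <- min(max(c0, lo), hi)
    return(data.frame(x_lo = x_lo, x_hi = x_hi, slope = 0, intercept = y))
  }
  # x where y crosses lo and hi
  cl <- (lo - c0) / s
  ch <- (hi - c0) / s
  cuts <- sort(c(x_lo, x_hi, pmin(pmax(c(cl, ch), x_lo), x_hi)))
  cuts <- unique(cuts)
  segs <- data.frame(x_lo = cuts[-length(cuts)], x_hi = cuts[-1])
  segs <- segs[segs$x_hi > segs$x_lo, , drop = FALSE]
  mid <- (segs$x_lo + segs$x_hi) / 2
  y_mid <- s * mid + c0
  segs$slope <- ifelse(y_mid < lo | y_mid > hi, 0, s)
  segs$intercept <- ifelse(y_mid < lo, lo, ifelse(y_mid > hi, hi, c0))
  segs
}

#' One-parameter bifurcation scan
#'
#' Perturbs the map along a built-in family and records, per parameter
#' value, the fixed-point analysis and (when power iteration converges) the
#' invariant density of the perturbed transfer matrix. The two families are
#'
#' * `pull_to_identity`: `S_beta(x) = (1 - beta) S(x) + beta x`,
#'   `beta` in `[0, 1]` -- interpolates from the fitted dynamics to frozen
#'   (identity) dynamics, stabilising fixed points as `beta` grows;
#' * `additive_shift`: `S_beta(x) = clip(S(x) + beta)` -- a uniform
#'   up/down-regulation of next-day expression, clipped to the domain.
#'
#' A user-supplied list of maps can be scanned instead via `maps`.
#'
#' @param map a `pwl_map`.
#' @param family `"pull_to_identity"` or `"additive_shift"`.
#' @param param_values ascending numeric parameter values.
#' @param maps optional explicit list of `pwl_map`s overriding the family.
#' @return a `pwl_bifurcation` : list with `param_values`, `fixed_points`
#'   (list of `pwl_fixed_points`), `invariant_densities` (list of
#'   `pwl_density` or `NULL` where power iteration failed).
#' @export
bifurcation_scan <- function(map, family = c("pull_to_identity", "additive_shift"),
                             param_values, maps = NULL) {
  pwl_assert(is.numeric(param_values) && length(param_values) >= 1,
             "validation", "`param_values` must be non-empty")
  pwl_assert(!is.unsorted(param_values, strictly = TRUE), "validation",
             "`param_values` must be strictly ascending")
  if (is.null(maps)) {
    maps <- lapply(param_values, function(beta) perturb_map(map, family, beta))
  } else {
    pwl_assert(length(maps) == length(param_values), "validation",
               "`maps` must match `param_values` in length")
  }
  fps <- lapply(maps, find_fixed_points)
  invs <- lapply(maps, function(m) {
    tryCatch(invariant_density(transfer_matrix_of_map(m), tol = 1e-9,
                               max_iter = 5000L),
             pwlmap_error = function(e) NULL)
  })
  structure(list(param_values = param_values, fixed_points = fps,
                 invariant_densities = invs, maps = maps),
            class = "pwl_bifurcation")
}

#' @export
print.pwl_bifurcation <- function(x, ...) {
  cat(sprintf("<pwl_bifurcation> %d parameter values in [%g, %g]\n",
              length(x$param_values), min(x$param_values), max(x$param_values)))
  for (k in seq_along(x$param_values)) {
    pts <- x$fixed_points[[k]]$points
    cat(sprintf("  beta = %-8g fixed points: %s\n", x$param_values[k],
                if (nrow(pts) == 0) "none"
                else paste(sprintf("%.4g (%s)", pts$x_star,
                                   ifelse(pts$stable, "stable", "unstable")),
                           collapse = ", ")))
  }
  invisible(x)
}
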