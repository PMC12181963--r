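#' Piecewise-constant probability densities
#'
#' A `pwl_density` stores per-cell density heights (probability per
#' log10-intensity unit) on a [partition()]. Heights are non-negative and the
#' total integral `sum(height * width)` is 1 to within 1e-9; constructors
#' renormalise exact-arithmetic drift but refuse grossly unnormalised input.
#'
#' @param p a `pwl_partition`.
#' @param values per-cell heights, length `p$n`.
#' @return a `pwl_density`.
#' @export
pwc_density <- function(p, values) {
  pwl_assert(is_partition(p), "validation", "`p` must be a pwl_partition")
  values <- as.numeric(values)
  pwl_assert(length(values) == p$n, "validation",
             sprintf("expected %d heights, got %d", p$n, length(values)))
  pwl_assert(all(is.finite(values)) && all(values >= 0), "validation",
             "density heights must be finite and non-negative")
  total <- sum(values * cell_widths(p))
  pwl_assert(abs(total - 1) <= 1e-6, "validation",
             sprintf("density integrates to %.8g, not 1", total))
  values <- values / total   # absorb float drift; no-op when total == 1
  structure(list(partition = p, values = values), class = "pwl_density")
}

#' @rdname pwc_density
#' @export
uniform_density <- function(p) {
  pwc_density(p, rep(1 / (p$hi - p$lo), p$n))
}

#' @export
print.pwl_density <- function(x, ...) {
  cat(sprintf("<pwl_density> on %d cells, [%g, %g]; mass by cell:\n",
              x$partition$n, x$partition$lo, x$partition$hi))
  print(signif(x$values * cell_widths(x$partition), 4))
  invisible(x)
}

# mass vector m_i = f_i * w_i (sums to 1)
mass_of <- function(f) f$values * cell_widths(f$partition)

density_from_mass <- function(p, m) {
  m <- pmax(m, 0)
  pwc_density(p, m / sum(m) / cell_widths(p))
}

#' Histogram density estimate from log-scale events
#'
#' Bins log10-intensity events into the partition cells and normalises so the
#' result integrates to 1. No kernel smoothing is applied: the histogram is
#' the natural representation for the transfer-matrix machinery and avoids an
#' uncontrolled bandwidth parameter.
#'
#' @param sample numeric vector of log10 intensities, or an
#'   [intensity_sample].
#' @param p a `pwl_partition`.
#' @param out_of_range `"drop"` discards events outside `[lo, hi)`;
#'   `"clip"` moves them to the nearest in-domain cell.
#' @return a `pwl_density`.
#' @export
estimate_density <- function(sample, p, out_of_range = c("drop", "clip")) {
  out_of_range <- match.arg(out_of_range)
  x <- if (inherits(sample, "intensity_sample")) sample$values else as.numeric(sample)
  pwl_assert(is_partition(p), "validation", "`p` must be a pwl_partition")
  x <- x[is.finite(x)]
  if (out_of_range == "clip") {
    eps <- (p$hi - p$lo) * 1e-12
    x <- pmin(pmax(x, p$lo), p$hi - eps)
  } else {
    x <- x[x >= p$lo & x < p$hi]
  }
  pwl_assert(length(x) > 0, "empty_input",
             "no in-range events left to estimate a density from")
  idx <- cell_index_of(p, x)
  counts <- tabulate(idx, nbins = p$n)
  pwc_density(p, counts / sum(counts) / cell_widths(p))
}

#' L1 distance between two densities
#'
#' The integral of `|a - b|` over the domain: 0 for identical densities and
#' at most 2 (disjoint supports). Both densities must share one partition.
#'
#' @param a,b `pwl_density` objects on the same partition.
#' @return non-negative scalar.
#' @export
l1_distance <- function(a, b) {
  pwl_assert(inherits(a, "pwl_density") && inherits(b, "pwl_density"),
             "validation", "both arguments must be pwl_density objects")
  check_same_partition(a$partition, b$partition)
  sum(abs(a$values - b$values) * cell_widths(a$partition))
}

#' A dated series of densities for one sorted fraction
#'
#' @param fraction_label fraction name, e.g. `"negative"`, `"low"`,
#'   `"medium"`, `"high"`.
#' @param days strictly increasing integer day indices (measurements are
#'   24 h apart; gaps are tolerated here and rejected at inference time).
#' @param densities list of `pwl_density`, one per day, all on one partition.
#' @return a `pwl_density_series`.
#' @export
density_series <- function(fraction_label, days, densities) {
  days <- as.integer(days)
  pwl_assert(length(days) == length(densities) && length(days) >= 1,
             "validation", "`days` and `densities` must have equal positive length")
  pwl_assert(all(diff(days) > 0), "validation", "`days` must be strictly increasing")
  pwl_assert(all(vapply(densities, inherits, TRUE, "pwl_density")),
             "validation", "`densities` must all be pwl_density objects")
  p <- densities[[1]]$partition
  for (f in densities) check_same_partition(p, f$partition)
  structure(list(fraction_label = as.character(fraction_label),
                 days = days, densities = densities, partition = p),
            class = "pwl_density_series")
}

#' @export
print.pwl_density_series <- function(x, ...) {
  cat(sprintf("<pwl_density_series> fraction '%s', days %s, %d cells\n",
              x$fraction_label, paste(range(x$days), collapse = ".."),
              x$partition$n))
  invisible(x)
}
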