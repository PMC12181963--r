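#' Cell ensembles and noise models
#'
#' An `pwl_ensemble` is a sample of per-cell log10 intensities at one time
#' step -- the population-level carrier of the state variable the map acts
#' on. A `noise_model` describes the additive perturbation applied after
#' the deterministic map: `x(t+1) = S(x(t)) + eta`, with `eta ~ N(0,
#' sigma^2)` on the log scale, and a boundary policy for perturbations that
#' leave the domain (`reflect` default; `clip` creates boundary atoms).
#'
#' @param values numeric log10 intensities in `[lo, hi)`.
#' @param day integer day index.
#' @export
ensemble <- function(values, day = 0L) {
  structure(list(values = as.numeric(values), day = as.integer(day)),
            class = "pwl_ensemble")
}

#' @export
print.pwl_ensemble <- function(x, ...) {
  cat(sprintf("<pwl_ensemble> %d cells at day %d\n", length(x$values), x$day))
  invisible(x)
}

#' @rdname ensemble
#' @param family `"none"` or `"gaussian"`.
#' @param sigma noise sd in log10-intensity units (0 when family is none).
#' @param boundary `"reflect"` or `"clip"`.
#' @export
noise_model <- function(family = c("none", "gaussian"), sigma = 0,
                        boundary = c("reflect", "clip")) {
  family <- match.arg(family)
  boundary <- match.arg(boundary)
  pwl_assert(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
             "validation", "`sigma` must be >= 0")
  if (family == "none")
    pwl_assert(sigma == 0, "validation", "family 'none' requires sigma == 0")
  structure(list(family = family, sigma = sigma, boundary = boundary),
            class = "pwl_noise_model")
}

#' Sample an ensemble from a piecewise-constant density
#'
#' Draws each cell's position by first choosing a partition cell with
#' probability equal to its mass, then uniformly within the cell. Fixed
#' `seed` gives bit-identical output.
#'
#' @param f a `pwl_density`.
#' @param n number of draws (`n = 0` returns an empty ensemble).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param day day stamp for the resulting ensemble.
#' @return a `pwl_ensemble`.
#' @export
sample_from_density <- function(f, n, seed = NULL, day = 0L) {
  pwl_assert(is.numeric(n) && length(n) == 1 && n >= 0, "validation",
             "`n` must be a non-negative count")
  p <- f$partition
  if (n == 0) return(ensemble(numeric(0), day))
  with_seed(seed, {
    idx <- sample.int(p$n, size = n, replace = TRUE, prob = mass_of(f))
    u <- runif(n)
    ensemble(p$edges[idx] + u * cell_widths(p)[idx], day)
  })
}

# Fold values into [lo, hi) by reflection at both walls; errors after
# max_reflections full folds (pathologically large sigma).
reflect_into <- function(x, lo, hi, max_reflections = 10L) {
  for (r in seq_len(max_reflections)) {
    below <- x < lo
    x[below] <- 2 * lo - x[below]
    above <- x > hi
    x[above] <- 2 * hi - x[above]
    if (!any(x < lo | x > hi)) {
      # hi itself is excluded from the half-open domain
      x[x == hi] <- hi - (hi - lo) * 1e-15
      return(x)
    }
  }
  pwl_stop("boundary",
           sprintf("%d value(s) still out of domain after %d reflections (sigma too large for the domain?)",
                   sum(x < lo | x > hi), max_reflections))
}

#' Advance an ensemble one day
#'
#' Applies the map to every cell and adds the noise term:
#' `x <- S(x) + eta`. The day stamp is incremented. With `family = "none"`
#' this is the deterministic model exactly.
#'
#' @param map a `pwl_map`.
#' @param e a `pwl_ensemble` with values in the map domain.
#' @param noise a `noise_model`.
#' @param seed integer seed for the noise draws, or `NULL`.
#' @return a `pwl_ensemble` at `day + 1`.
#' @export
step_ensemble <- function(map, e, noise = noise_model("none"), seed = NULL) {
  pwl_assert(inherits(e, "pwl_ensemble"), "validation", "`e` must be a pwl_ensemble")
  lo <- map$partition$lo; hi <- map$partition$hi
  y <- apply_map(map, e$values)
  y[y >= hi] <- hi - (hi - lo) * 1e-15
  if (noise$family == "gaussian" && noise$sigma > 0) {
    y <- with_seed(seed, y + rnorm(length(y), sd = noise$sigma))
    y <- if (noise$boundary == "reflect") reflect_into(y, lo, hi)
         else pmin(pmax(y, lo), hi - (hi - lo) * 1e-15)
  }
  ensemble(y, e$day + 1L)
}

#' Monte-Carlo prediction of a density time series
#'
#' Mirrors the experimental forecasting loop: each day, sample `n` initial
#' conditions from the previous day's *density*, push them through the map
#' (plus noise), and re-estimate a density. Re-sampling from the density
#' rather than carrying the raw ensemble matches the stated procedure;
#' `carry_ensemble = TRUE` enables the lower-variance alternative. Per-day
#' RNG streams are split from the master seed, so day `k` is reproducible
#' independent of `n`.
#'
#' @param map a `pwl_map`.
#' @param f0 initial `pwl_density` on the map partition.
#' @param days number of days to predict (>= 1).
#' @param n ensemble size per day (floor 1000 for meaningful densities).
#' @param noise a `noise_model`.
#' @param seed master integer seed.
#' @param carry_ensemble logical; carry cells between days instead of
#'   re-sampling.
#' @param start_day day stamp of `f0` (predictions are `start_day + 1 ...`).
#' @return a `pwl_density_series` with days `start_day ... start_day + days`
#'   (the initial density included first).
#' @export
predict_density_series <- function(map, f0, days, n = 1e5,
                                   noise = noise_model("none"), seed = 1L,
                                   carry_ensemble = FALSE, start_day = 0L) {
  pwl_assert(days >= 1, "validation", "`days` must be >= 1")
  pwl_assert(n >= 1000, "validation", "`n` must be >= 1000 for a meaningful density")
  check_same_partition(map$partition, f0$partition)
  dens <- vector("list", days + 1L)
  dens[[1]] <- f0
  e <- NULL
  for (d in seq_len(days)) {
    sd1 <- derive_seed(seed, 2L * d)
    sd2 <- derive_seed(seed, 2L * d + 1L)
    if (is.null(e) || !carry_ensemble)
      e <- sample_from_density(dens[[d]], n, seed = sd1, day = start_day + d - 1L)
    e <- step_ensemble(map, e, noise, seed = sd2)
    dens[[d + 1L]] <- estimate_density(e$values, map$partition, out_of_range = "clip")
  }
  density_series("predicted", start_day + 0:days, dens)
}
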