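#' Sorting gates
#'
#' A gate is a half-open log10-intensity interval used to isolate a sorted
#' fraction. The default layout is four equal-width gates spanning the
#' domain, labelled negative / low / medium / high.
#'
#' @param label gate name.
#' @param lo,hi gate bounds (half-open `[lo, hi)`).
#' @export
sorting_gate <- function(label, lo, hi) {
  pwl_assert(lo < hi, "validation", "gate needs lo < hi")
  structure(list(label = as.character(label), lo = lo, hi = hi),
            class = "pwl_sorting_gate")
}

#' @rdname sorting_gate
#' @param p a `pwl_partition` giving the domain to split.
#' @param labels gate labels, low to high intensity.
#' @export
default_gates <- function(p, labels = c("negative", "low", "medium", "high")) {
  k <- length(labels)
  cuts <- seq(p$lo, p$hi, length.out = k + 1)
  lapply(seq_len(k), function(i) sorting_gate(labels[i], cuts[i], cuts[i + 1]))
}

#' Ground-truth maps for synthetic experiments
#'
#' Stand-ins for an unpublished fitted map: `tent` and `skew_tent` are
#' canonical chaotic maps with known (uniform) invariant density, rescaled
#' to the partition domain; `random_semi_markov` draws a transfer matrix
#' with independent Dirichlet(1, ..., 1) rows and realises it via
#' [construct_semi_markov_map()].
#'
#' @param kind `"tent"`, `"skew_tent"`, or `"random_semi_markov"`.
#' @param p partition the map lives on (default 16 cells on `[0, 4]`).
#' @param peak skew-tent peak location as a fraction of the domain
#'   (`tent` is `peak = 0.5`).
#' @param seed integer seed (used by `random_semi_markov`).
#' @return a `pwl_map`.
#' @export
make_ground_truth_map <- function(kind = c("tent", "skew_tent", "random_semi_markov"),
                                  p = partition(0, 4, 16), peak = 0.25,
                                  seed = NULL) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) pwl_stop("validation",
                                                sprintf("unknown map kind '%s'", kind[1])))
  lo <- p$lo; hi <- p$hi; L <- hi - lo
  if (kind == "tent") peak <- 0.5
  if (kind %in% c("tent", "skew_tent")) {
    pwl_assert(peak > 0 && peak < 1, "validation", "`peak` must be in (0, 1)")
    xp <- lo + peak * L
    up <- 1 / peak          # rises lo -> hi over [lo, xp)
    dn <- -1 / (1 - peak)   # falls hi -> lo over [xp, hi)
    branches <- data.frame(
      x_lo = c(lo, xp), x_hi = c(xp, hi),
      slope = c(up, dn),
      intercept = c(lo - up * lo, lo - dn * hi))
    return(pwl_map(p, branches))
  }
  with_seed(seed, {
    Q <- matrix(rexp(p$n * p$n), p$n, p$n)   # Dirichlet(1,...,1) rows
    Q <- Q / rowSums(Q)
    construct_semi_markov_map(transfer_matrix(p, Q))
  })
}

#' Simulate the cell-sorting experiment
#'
#' Emulates the sorted-fraction time-course design: a parental population
#' is burned in to the map's long-run ensemble (default 50 steps from a
#' uniform start, under the same noise model), each gate captures its
#' sorted fraction on day 0, and every fraction is then advanced daily with
#' [step_ensemble()], recording a density per day. Optionally emits raw
#' per-day event tables on the linear intensity scale with log-normal
#' measurement noise (additive Gaussian on the log scale, default sd 0.05
#' decades), separate from the dynamical noise.
#'
#' @param map ground-truth `pwl_map`.
#' @param gates list of [sorting_gate()]s (default [default_gates()]).
#' @param n_cells parental population size (>= 1000).
#' @param days number of post-sort days to follow (>= 2); each series holds
#'   `days + 1` densities (day 0 .. days).
#' @param noise dynamical `noise_model`.
#' @param seed master seed.
#' @param burn_in parental burn-in steps.
#' @param event_tables logical; also return per-day raw intensity samples.
#' @param measurement_sigma measurement noise sd (log10 decades) for event
#'   tables.
#' @return a `pwl_experiment_bundle`: list with `truth_map`, `truth_sigma`,
#'   `series` (named list of `pwl_density_series`), `gates`, and optional
#'   `event_tables` (`events[[fraction]][[day]]` = linear intensities).
#' @export
simulate_sorting_experiment <- function(map, gates = default_gates(map$partition),
                                        n_cells = 20000, days = 5,
                                        noise = noise_model("none"), seed = 1L,
                                        burn_in = 50L, event_tables = FALSE,
                                        measurement_sigma = 0.05) {
  pwl_assert(length(gates) >= 1, "validation", "need at least one gate")
  pwl_assert(days >= 2, "validation", "`days` must be >= 2")
  pwl_assert(n_cells >= 1000, "validation", "`n_cells` must be >= 1000")
  p <- map$partition
  for (g in gates)
    pwl_assert(g$lo >= p$lo && g$hi <= p$hi, "validation",
               sprintf("gate '%s' outside the domain", g$label))
  parent <- sample_from_density(uniform_density(p), n_cells,
                                seed = derive_seed(seed, 0L))
  for (bstep in seq_len(burn_in))
    parent <- step_ensemble(map, parent, noise, seed = derive_seed(seed, 100L + bstep))
  parent$day <- 0L
  series <- list()
  events <- list()
  for (gi in seq_along(gates)) {
    g <- gates[[gi]]
    vals <- parent$values[parent$values >= g$lo & parent$values < g$hi]
    pwl_assert(length(vals) > 0, "empty_gate",
               sprintf("gate '%s' [%g, %g) captured no cells from the burned-in population",
                       g$label, g$lo, g$hi))
    # each sorted fraction is its own subculture, assayed at full event
    # depth daily: renormalise the gated day-0 density and carry n_cells
    f0 <- estimate_density(vals, p)
    e <- sample_from_density(f0, n_cells, seed = derive_seed(seed, 5000L + gi), day = 0L)
    dens <- vector("list", days + 1L)
    dens[[1]] <- estimate_density(e$values, p)
    raw <- if (event_tables) vector("list", days + 1L) else NULL
    if (event_tables)
      raw[[1]] <- measured_intensities(e$values, measurement_sigma,
                                       derive_seed(seed, 1000L * gi))
    for (d in seq_len(days)) {
      e <- step_ensemble(map, e, noise, seed = derive_seed(seed, 1000L * gi + d))
      dens[[d + 1L]] <- estimate_density(e$values, p)
      if (event_tables)
        raw[[d + 1L]] <- measured_intensities(e$values, measurement_sigma,
                                              derive_seed(seed, 1000L * gi + 500L + d))
    }
    series[[g$label]] <- density_series(g$label, 0:days, dens)
    if (event_tables) events[[g$label]] <- raw
  }
  structure(list(truth_map = map,
                 truth_sigma = if (noise$family == "gaussian") noise$sigma else 0,
                 series = series, gates = gates,
                 event_tables = if (event_tables) events else NULL),
            class = "pwl_experiment_bundle")
}

# log-intensity -> measured linear intensity with log-normal noise
measured_intensities <- function(logx, sigma, seed) {
  with_seed(seed, 10^(logx + if (sigma > 0) rnorm(length(logx), sd = sigma) else 0))
}

#' @export
print.pwl_experiment_bundle <- function(x, ...) {
  cat(sprintf("<pwl_experiment_bundle> %d fractions (%s), days 0..%d, truth sigma %g\n",
              length(x$series), paste(names(x$series), collapse = ", "),
              max(x$series[[1]]$days), x$truth_sigma))
  invisible(x)
}

#' Score an inference result against the generating truth
#'
#' @param bundle a `pwl_experiment_bundle`.
#' @param result a `pwl_inference_result` fitted to the bundle's series.
#' @param fp_match_tol fixed points closer than this (log10 units) count as
#'   matched (default 0.05).
#' @return a `pwl_recovery_report`: entrywise max and Frobenius error of
#'   `Q_hat` vs the truth transfer matrix, L1 error of invariant densities,
#'   fixed-point matching counts, and sigma error when both are available.
#' @export
recovery_report <- function(bundle, result, fp_match_tol = 0.05) {
  pwl_assert(inherits(bundle, "pwl_experiment_bundle"), "validation",
             "`bundle` must be a pwl_experiment_bundle")
  pwl_assert(inherits(result, "pwl_inference_result"), "validation",
             "`result` must be a pwl_inference_result")
  check_same_partition(bundle$truth_map$partition, result$Q_hat$partition)
  Q_true <- transfer_matrix_of_map(bundle$truth_map)
  dQ <- result$Q_hat$Q - Q_true$Q
  inv_err <- tryCatch(
    l1_distance(invariant_density(result$Q_hat, tol = 1e-9, max_iter = 5000L),
                invariant_density(Q_true, tol = 1e-9, max_iter = 5000L)),
    pwlmap_error = function(e) NA_real_)
  fp_true <- find_fixed_points(bundle$truth_map)$points$x_star
  fp_hat <- find_fixed_points(result$map)$points$x_star
  matched <- 0L
  if (length(fp_true) && length(fp_hat))
    matched <- sum(vapply(fp_true,
                          function(x) any(abs(fp_hat - x) <= fp_match_tol),
                          logical(1)))
  sigma_err <- if (!is.na(result$sigma_hat)) abs(result$sigma_hat - bundle$truth_sigma)
               else NA_real_
  structure(list(q_max_err = max(abs(dQ)),
                 q_frobenius_err = sqrt(sum(dQ^2)),
                 invariant_l1_err = inv_err,
                 n_fixed_true = length(fp_true), n_fixed_hat = length(fp_hat),
                 n_fixed_matched = matched,
                 sigma_err = sigma_err),
            class = "pwl_recovery_report")
}

#' @export
print.pwl_recovery_report <- function(x, ...) {
  cat("<pwl_recovery_report>\n")
  cat(sprintf("  Q entrywise max error : %.4g\n", x$q_max_err))
  cat(sprintf("  Q Frobenius error     : %.4g\n", x$q_frobenius_err))
  cat(sprintf("  invariant density L1  : %.4g\n", x$invariant_l1_err))
  cat(sprintf("  fixed points matched  : %d / %d (found %d)\n",
              x$n_fixed_matched, x$n_fixed_true, x$n_fixed_hat))
  if (!is.na(x$sigma_err)) cat(sprintf("  |sigma error|         : %.4g\n", x$sigma_err))
  invisible(x)
}
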