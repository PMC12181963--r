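#' Run configuration
#'
#' Single configuration object for the end-to-end pipeline. Can be built
#' from a JSON file (per-stage sections) or from defaults with overrides.
#' Every referenced module precondition is validated here, before dispatch.
#'
#' @param path optional JSON config file.
#' @param ... named overrides of the defaults (see source for the full
#'   list: partition lo/hi/n_cells, map_kind, n_cells, days, ridge,
#'   sigma_grid, noise family/sigma, seed, sim_days, sim_n).
#' @return a `pwl_run_config` (named list).
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    lo = 0, hi = 4, n_cells_partition = 16,
    map_kind = "random_semi_markov",
    n_cells = 20000, days = 5,
    noise = list(family = "none", sigma = 0, boundary = "reflect"),
    ridge = 1e-6, sigma_grid = NULL,
    sim_days = 5, sim_n = 100000,
    seed = 1L)
  if (!is.null(path)) {
    pwl_assert(file.exists(path), "io", sprintf("config not found: %s", path))
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  # validate downstream preconditions up front
  pwl_assert(cfg$lo < cfg$hi && cfg$n_cells_partition >= 2, "validation",
             "config: invalid partition spec")
  pwl_assert(cfg$days >= 2, "validation",
             "config: `days` must be >= 2 (the infer stage needs consecutive day pairs)")
  pwl_assert(cfg$n_cells >= 1000, "validation", "config: `n_cells` must be >= 1000")
  pwl_assert(cfg$ridge >= 0, "validation", "config: `ridge` must be >= 0")
  if (!is.null(cfg$sigma_grid))
    pwl_assert(all(cfg$sigma_grid >= 0), "validation",
               "config: `sigma_grid` values must be >= 0")
  structure(cfg, class = "pwl_run_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

out_path <- function(out_dir, name, force) {
  path <- file.path(out_dir, name)
  pwl_assert(force || !file.exists(path), "io",
             sprintf("refusing to overwrite %s (use force = TRUE / --force)", path))
  path
}

#' Run the full synthetic pipeline
#'
#' synth -> infer -> analyze -> simulate -> recovery report. Writes the
#' truth and fitted map JSONs, observed and predicted density CSVs, the
#' analysis and recovery reports, and a manifest listing the config, seed,
#' and md5 of every artifact. All randomness flows from `config$seed`, so a
#' rerun with the same config reproduces every hash.
#'
#' @param config a `pwl_run_config`.
#' @param out_dir output directory (created if missing).
#' @param force overwrite existing artifacts.
#' @return invisibly, the manifest list.
#' @export
cmd_pipeline <- function(config = run_config(), out_dir = "pwlmap_run",
                         force = FALSE) {
  pwl_assert(inherits(config, "pwl_run_config"), "validation",
             "`config` must come from run_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- partition(config$lo, config$hi, config$n_cells_partition)
  noise <- noise_model(config$noise$family, config$noise$sigma %||% 0,
                       config$noise$boundary %||% "reflect")

  stage_log("synth", "truth map (%s) + sorting experiment: %d cells, %d days",
            config$map_kind, config$n_cells, config$days)
  truth <- make_ground_truth_map(config$map_kind, p = p, seed = config$seed)
  bundle <- simulate_sorting_experiment(truth, n_cells = config$n_cells,
                                        days = config$days, noise = noise,
                                        seed = config$seed)
  truth_json <- out_path(out_dir, "truth_map.json", force)
  write_map_json(truth, truth_json)
  obs_csv <- out_path(out_dir, "observed_densities.csv", force)
  write_density_series(unname(bundle$series), obs_csv)

  stage_log("infer", "fitting transfer matrix (ridge %g%s)", config$ridge,
            if (is.null(config$sigma_grid)) ""
            else sprintf(", sigma grid {%s}", paste(config$sigma_grid, collapse = ", ")))
  fit <- if (is.null(config$sigma_grid))
    infer_map_from_series(bundle$series, ridge = config$ridge)
  else fit_noise_sigma(bundle$series, config$sigma_grid, ridge = config$ridge)
  fit_json <- out_path(out_dir, "fitted_map.json", force)
  write_map_json(fit$map, fit_json)

  stage_log("analyze", "fixed points + Lyapunov exponent of the fitted map")
  fps <- find_fixed_points(fit$map)
  finv <- tryCatch(invariant_density(fit$Q_hat, tol = 1e-9, max_iter = 5000L),
                   pwlmap_error = function(e) NULL)
  lyap <- if (!is.null(finv)) lyapunov_exponent(fit$map, finv) else NA_real_
  report <- list(
    n_pairs = fit$n_pairs, residual = fit$residual,
    sigma_hat = if (is.na(fit$sigma_hat)) NULL else fit$sigma_hat,
    per_pair_l1 = fit$per_pair_l1,
    fixed_points = fps$points,
    lyapunov_exponent = lyap)
  report_json <- out_path(out_dir, "fit_report.json", force)
  jsonlite::write_json(report, report_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")

  stage_log("simulate", "predicting %d days at n = %d from each fraction's day-0 density",
            config$sim_days, config$sim_n)
  preds <- lapply(names(bundle$series), function(fr) {
    s <- predict_density_series(fit$map, bundle$series[[fr]]$densities[[1]],
                                days = config$sim_days, n = config$sim_n,
                                noise = noise,
                                seed = derive_seed(config$seed, 7L + match(fr, names(bundle$series))))
    s$fraction_label <- fr
    s
  })
  pred_csv <- out_path(out_dir, "predicted_densities.csv", force)
  write_density_series(preds, pred_csv)

  stage_log("compare", "scoring recovery against the generating truth")
  rec <- recovery_report(bundle, fit)
  rec_json <- out_path(out_dir, "recovery_report.json", force)
  jsonlite::write_json(unclass(rec), rec_json, auto_unbox = TRUE, digits = NA,
                       na = "null")

  artifacts <- c(truth_json, obs_csv, paste0(obs_csv, ".partition.json"),
                 fit_json, report_json, pred_csv,
                 paste0(pred_csv, ".partition.json"), rec_json)
  manifest <- list(config = unclass(config), seed = config$seed,
                   artifacts = lapply(artifacts, function(a)
                     list(path = basename(a), md5 = unname(tools::md5sum(a)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("done", "artifacts in %s", out_dir)
  invisible(manifest)
}

#' Diagnostic plots
#'
#' `plot_map` draws the map branches against the diagonal `y = x` with
#' fixed points marked (the cobweb-style view); `plot_density_overlay`
#' overlays observed and predicted densities per day. `cmd_plot` is the
#' file-based wrapper used by the CLI: map JSON + density CSVs in, a
#' multi-page PDF out.
#'
#' @param map a `pwl_map`.
#' @param main plot title.
#' @export
plot_map <- function(map, main = "Piecewise-linear map") {
  p <- map$partition
  graphics::plot(NULL, xlim = c(p$lo, p$hi), ylim = c(p$lo, p$hi),
                 xlab = "log10 intensity, day n", ylab = "log10 intensity, day n+1",
                 main = main, asp = 1)
  graphics::abline(0, 1, col = "red")
  b <- map$branches
  for (k in seq_len(nrow(b)))
    graphics::segments(b$x_lo[k], b$slope[k] * b$x_lo[k] + b$intercept[k],
                       b$x_hi[k], b$slope[k] * b$x_hi[k] + b$intercept[k],
                       lwd = 2, col = "steelblue")
  fps <- find_fixed_points(map)$points
  if (nrow(fps))
    graphics::points(fps$x_star, fps$x_star, pch = ifelse(fps$stable, 19, 1),
                     col = "darkred", cex = 1.3)
  invisible(fps)
}

#' @rdname plot_map
#' @param observed,predicted `pwl_density_series` on one partition.
#' @export
plot_density_overlay <- function(observed, predicted) {
  check_same_partition(observed$partition, predicted$partition)
  days <- intersect(observed$days, predicted$days)
  pwl_assert(length(days) > 0, "validation", "series share no days")
  cen <- cell_centers(observed$partition)
  for (d in days) {
    fo <- observed$densities[[match(d, observed$days)]]
    fp <- predicted$densities[[match(d, predicted$days)]]
    ylim <- c(0, max(fo$values, fp$values) * 1.05)
    graphics::plot(cen, fo$values, type = "s", col = "red", lwd = 2,
                   ylim = ylim, xlab = "log10 intensity", ylab = "density",
                   main = sprintf("%s: day %d", observed$fraction_label, d))
    graphics::lines(cen, fp$values, type = "s", col = "blue", lwd = 2)
    graphics::legend("topright", c("observed", "predicted"),
                     col = c("red", "blue"), lwd = 2, bty = "n")
  }
  invisible(NULL)
}

#' @rdname plot_map
#' @param map_json path to a map JSON.
#' @param observed_csv,predicted_csv long-format density CSVs (predicted
#'   optional).
#' @param out_pdf output PDF path.
#' @param force overwrite.
#' @export
cmd_plot <- function(map_json, observed_csv = NULL, predicted_csv = NULL,
                     out_pdf = "pwlmap_plots.pdf", force = FALSE) {
  map <- read_map_json(map_json)
  obs <- if (!is.null(observed_csv)) read_density_series(observed_csv)
  pred <- if (!is.null(predicted_csv)) read_density_series(predicted_csv)
  pwl_assert(force || !file.exists(out_pdf), "io",
             sprintf("refusing to overwrite %s", out_pdf))
  grDevices::pdf(out_pdf, width = 7, height = 6)
  on.exit(grDevices::dev.off())
  plot_map(map)
  if (!is.null(obs) && !is.null(pred))
    for (fr in intersect(names(obs), names(pred)))
      plot_density_overlay(obs[[fr]], pred[[fr]])
  else if (!is.null(obs))
    for (fr in names(obs))
      plot_density_overlay(obs[[fr]], obs[[fr]])
  invisible(out_pdf)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `infer`, `analyze`, `simulate`, `plot`,
#' `pipeline`. Shared flags: `--config`, `--out-dir`, `--seed`, `--force`.
#' Install target: `inst/cli/pwlmap` (an Rscript shim calling this
#' function).
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
pwlmap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pwlmap <synth|infer|analyze|simulate|plot|pipeline> [options]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--out-dir", type = "character", default = "pwlmap_run",
                            dest = "out_dir"),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--force", action = "store_true", default = FALSE),
      optparse::make_option("--map", type = "character", default = NULL,
                            help = "map JSON (infer/analyze/simulate/plot)"),
      optparse::make_option("--densities", type = "character", default = NULL,
                            help = "long-format density CSV"),
      optparse::make_option("--predicted", type = "character", default = NULL))),
    args = args[-1])
  status <- tryCatch({
    cfg <- run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- opts$seed
    dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
    switch(cmd,
      pipeline = cmd_pipeline(cfg, opts$out_dir, force = opts$force),
      synth = {
        p <- partition(cfg$lo, cfg$hi, cfg$n_cells_partition)
        truth <- make_ground_truth_map(cfg$map_kind, p = p, seed = cfg$seed)
        noise <- noise_model(cfg$noise$family, cfg$noise$sigma %||% 0)
        bundle <- simulate_sorting_experiment(truth, n_cells = cfg$n_cells,
                                              days = cfg$days, noise = noise,
                                              seed = cfg$seed)
        write_map_json(truth, out_path(opts$out_dir, "truth_map.json", opts$force))
        write_density_series(unname(bundle$series),
                             out_path(opts$out_dir, "observed_densities.csv", opts$force))
      },
      infer = {
        pwl_assert(!is.null(opts$densities), "validation", "infer needs --densities")
        series <- read_density_series(opts$densities)
        fit <- if (is.null(cfg$sigma_grid)) infer_map_from_series(series, cfg$ridge)
               else fit_noise_sigma(series, cfg$sigma_grid, cfg$ridge)
        write_map_json(fit$map, out_path(opts$out_dir, "fitted_map.json", opts$force))
        jsonlite::write_json(
          list(residual = fit$residual, n_pairs = fit$n_pairs,
               sigma_hat = if (is.na(fit$sigma_hat)) NULL else fit$sigma_hat,
               per_pair_l1 = fit$per_pair_l1),
          out_path(opts$out_dir, "fit_report.json", opts$force),
          auto_unbox = TRUE, digits = NA)
      },
      analyze = {
        pwl_assert(!is.null(opts$map), "validation", "analyze needs --map")
        map <- read_map_json(opts$map)
        Q <- transfer_matrix_of_map(map)
        finv <- invariant_density(Q, tol = 1e-9, max_iter = 5000L)
        jsonlite::write_json(
          list(fixed_points = find_fixed_points(map)$points,
               lyapunov_exponent = lyapunov_exponent(map, finv),
               invariant_density = finv$values),
          out_path(opts$out_dir, "analysis.json", opts$force),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
      },
      simulate = {
        pwl_assert(!is.null(opts$map) && !is.null(opts$densities), "validation",
                   "simulate needs --map and --densities")
        map <- read_map_json(opts$map)
        series <- read_density_series(opts$densities)
        noise <- noise_model(cfg$noise$family, cfg$noise$sigma %||% 0)
        preds <- lapply(names(series), function(fr) {
          s <- predict_density_series(map, series[[fr]]$densities[[1]],
                                      days = cfg$sim_days, n = cfg$sim_n,
                                      noise = noise,
                                      seed = derive_seed(cfg$seed, match(fr, names(series))))
          s$fraction_label <- fr
          s
        })
        write_density_series(preds,
                             out_path(opts$out_dir, "predicted_densities.csv", opts$force))
      },
      plot = {
        pwl_assert(!is.null(opts$map), "validation", "plot needs --map")
        cmd_plot(opts$map, opts$densities, opts$predicted,
                 out_pdf = file.path(opts$out_dir, "plots.pdf"), force = opts$force)
      },
      pwl_stop("validation", sprintf("unknown subcommand '%s'\n%s", cmd, usage)))
    0L
  }, pwlmap_error = function(e) {
    message(sprintf("pwlmap %s: error: %s", cmd, conditionMessage(e)))
    1L
  })
  invisible(status)
}
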