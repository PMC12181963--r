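#' Per-event fluorescence intensity samples
#'
#' Carrier for raw flow-cytometry event data: one fluorescence value per
#' cell-event, on the linear (or, after [log10_transform()], log10) scale.
#'
#' @param values numeric event intensities.
#' @param n_dropped events removed so far by a transform policy.
#' @export
intensity_sample <- function(values, n_dropped = 0L) {
  values <- as.numeric(values)
  structure(list(values = values, n_events = length(values),
                 n_dropped = as.integer(n_dropped)),
            class = "intensity_sample")
}

#' @export
print.intensity_sample <- function(x, ...) {
  cat(sprintf("<intensity_sample> %d events (%d dropped)\n",
              x$n_events, x$n_dropped))
  invisible(x)
}

#' Read one fluorescence channel from an event table
#'
#' Reads a CSV/TSV with a header row and one cell-event per row, and extracts
#' the named channel column. Delimiter is taken from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma). Cells that are empty or literal
#' `NA` are skipped; any other non-numeric cell is a parse error reporting
#' the offending row.
#'
#' @param path file path.
#' @param column channel column name as it appears in the header.
#' @return an [intensity_sample] of all finite values, in file order.
#' @export
load_intensity_table <- function(path, column) {
  pwl_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  pwl_assert(column %in% names(df), "schema",
             sprintf("column '%s' not found in %s (columns: %s)",
                     column, path, paste(names(df), collapse = ", ")))
  raw <- df[[column]]
  keep <- !(raw == "" | toupper(raw) == "NA")
  vals <- suppressWarnings(as.numeric(raw[keep]))
  if (anyNA(vals)) {
    bad_row <- which(keep)[which(is.na(vals))[1]]
    pwl_stop("parse",
             sprintf("non-numeric value '%s' in column '%s' at data row %d of %s",
                     raw[keep][is.na(vals)][1], column, bad_row, path),
             row = bad_row)
  }
  vals <- vals[is.finite(vals)]
  pwl_assert(length(vals) > 0, "empty_input",
             sprintf("no parseable events in column '%s' of %s", column, path))
  intensity_sample(vals)
}

#' Log10-transform raw intensities
#'
#' Flow cytometers can report non-positive compensated values; those cannot
#' be log-transformed directly. Under `policy = "drop"` they are removed (and
#' counted in `n_dropped`); under `"clamp"` they are raised to `floor` first.
#'
#' @param sample an [intensity_sample] on the linear scale.
#' @param policy `"drop"` or `"clamp"`.
#' @param floor positive clamping floor (linear scale), required for clamp.
#' @return an [intensity_sample] of log10 values.
#' @export
log10_transform <- function(sample, policy = c("drop", "clamp"), floor = NULL) {
  policy <- match.arg(policy)
  x <- if (inherits(sample, "intensity_sample")) sample$values else as.numeric(sample)
  prev_dropped <- if (inherits(sample, "intensity_sample")) sample$n_dropped else 0L
  if (policy == "clamp") {
    pwl_assert(is.numeric(floor) && length(floor) == 1 && floor > 0,
               "validation", "clamp policy requires a positive `floor`")
    x <- pmax(x, floor)
    dropped <- 0L
  } else {
    keep <- x > 0
    dropped <- sum(!keep)
    x <- x[keep]
    pwl_assert(length(x) > 0, "empty_input",
               "all events were non-positive; nothing left after drop")
  }
  intensity_sample(log10(x), n_dropped = prev_dropped + dropped)
}

#' Write / read density series in long format
#'
#' The long CSV has columns `fraction, day, cell_index, height` (cell_index
#' is 1-based). Heights are written with 17 significant digits so the
#' writer/reader pair round-trips bit-exactly. The partition is stored in a
#' JSON sidecar (`<path>.partition.json`) unless an explicit `partition_path`
#' is given.
#'
#' @param series a `pwl_density_series` or list of them.
#' @param path output CSV path.
#' @param partition_path where to write/read the partition edges JSON.
#' @return `write_density_series` returns `path` invisibly;
#'   `read_density_series` returns a named list of `pwl_density_series`.
#' @export
write_density_series <- function(series, path,
                                 partition_path = paste0(path, ".partition.json")) {
  if (inherits(series, "pwl_density_series")) series <- list(series)
  pwl_assert(length(series) >= 1, "empty_input", "no series to write")
  p <- series[[1]]$partition
  rows <- do.call(rbind, lapply(series, function(s) {
    check_same_partition(p, s$partition)
    do.call(rbind, lapply(seq_along(s$days), function(k) {
      data.frame(fraction = s$fraction_label, day = s$days[k],
                 cell_index = seq_len(p$n),
                 height = sprintf("%.17g", s$densities[[k]]$values),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(edges = p$edges), partition_path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_density_series
#' @export
read_density_series <- function(path,
                                partition_path = paste0(path, ".partition.json")) {
  pwl_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  pwl_assert(file.exists(partition_path), "io",
             sprintf("partition sidecar not found: %s", partition_path))
  p <- partition(edges = jsonlite::read_json(partition_path,
                                             simplifyVector = TRUE)$edges)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fraction", "day", "cell_index", "height")
  pwl_assert(all(need %in% names(df)), "schema",
             sprintf("density CSV must have columns %s", paste(need, collapse = ", ")))
  pwl_assert(nrow(df) > 0, "empty_input", sprintf("no rows in %s", path))
  out <- list()
  for (frac in unique(df$fraction)) {
    sub <- df[df$fraction == frac, ]
    days <- sort(unique(sub$day))
    dens <- lapply(days, function(d) {
      cells <- sub[sub$day == d, ]
      cells <- cells[order(cells$cell_index), ]
      pwl_assert(identical(cells$cell_index, seq_len(p$n)), "schema",
                 sprintf("fraction '%s' day %d: expected cell_index 1..%d", frac, d, p$n))
      pwc_density(p, as.numeric(cells$height))
    })
    out[[frac]] <- density_series(frac, days, dens)
  }
  out
}
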