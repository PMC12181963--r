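#' Piecewise-linear maps on the log-intensity domain
#'
#' A `pwl_map` is the deterministic one-step model `x(t+1) = S(x(t))` of
#' next-day marker expression: an ordered set of affine branches
#' `S(x) = slope * x + intercept` on half-open domain intervals
#' `[x_lo, x_hi)` that together tile the global domain `[lo, hi)` exactly.
#' Discontinuities at branch boundaries are permitted and expected.
#' Branch images must stay inside the closed domain to within 1e-9; images
#' are clipped to the domain after that check, so maps built to be exactly
#' onto are float-safe.
#'
#' @param p the `pwl_partition` whose domain the map acts on.
#' @param branches data.frame with columns `x_lo`, `x_hi`, `slope`,
#'   `intercept`, one row per branch.
#' @return a `pwl_map`.
#' @export
pwl_map <- function(p, branches) {
  pwl_assert(is_partition(p), "validation", "`p` must be a pwl_partition")
  need <- c("x_lo", "x_hi", "slope", "intercept")
  pwl_assert(is.data.frame(branches) && all(need %in% names(branches)),
             "validation", "`branches` needs columns x_lo, x_hi, slope, intercept")
  b <- branches[order(branches$x_lo), need, drop = FALSE]
  rownames(b) <- NULL
  pwl_assert(all(is.finite(as.matrix(b))), "validation", "branch fields must be finite")
  pwl_assert(all(b$x_lo < b$x_hi), "validation", "each branch needs x_lo < x_hi")
  tol <- 1e-9
  pwl_assert(abs(b$x_lo[1] - p$lo) <= tol && abs(b$x_hi[nrow(b)] - p$hi) <= tol,
             "invalid_map", "branch domains must span [lo, hi)")
  if (nrow(b) > 1) {
    gaps <- b$x_lo[-1] - b$x_hi[-nrow(b)]
    pwl_assert(all(abs(gaps) <= tol), "invalid_map",
               "branch domains must tile [lo, hi) with no gaps or overlaps")
  }
  # snap to an exact tiling so downstream geometry is watertight
  b$x_lo[1] <- p$lo
  b$x_hi[nrow(b)] <- p$hi
  if (nrow(b) > 1) b$x_lo[-1] <- b$x_hi[-nrow(b)]
  # image containment: endpoints of each branch image inside [lo, hi]
  ia <- b$slope * b$x_lo + b$intercept
  ib <- b$slope * b$x_hi + b$intercept
  img_lo <- pmin(ia, ib); img_hi <- pmax(ia, ib)
  pwl_assert(all(img_lo >= p$lo - tol) && all(img_hi <= p$hi + tol),
             "invalid_map",
             sprintf("branch image [%.6g, %.6g] escapes the domain [%g, %g]",
                     min(img_lo), max(img_hi), p$lo, p$hi))
  structure(list(partition = p, branches = b), class = "pwl_map")
}

#' @export
print.pwl_map <- function(x, ...) {
  cat(sprintf("<pwl_map> %d branches on [%g, %g)\n",
              nrow(x$branches), x$partition$lo, x$partition$hi))
  print(format(x$branches, digits = 4))
  invisible(x)
}

# branch index for each x in [lo, hi); NA outside
branch_index_of <- function(map, x) {
  b <- map$branches
  idx <- findInterval(x, c(b$x_lo, map$partition$hi))
  idx[x < map$partition$lo | x >= map$partition$hi] <- NA_integer_
  idx
}

#' Apply a piecewise-linear map
#'
#' Evaluates `S(x)` on the unique branch containing each `x`. Vectorised.
#' Results are clipped into the closed domain (branch validation already
#' bounds the overshoot by 1e-9).
#'
#' @param map a `pwl_map`.
#' @param x log10 intensities in `[lo, hi)`.
#' @return numeric vector `S(x)`.
#' @export
apply_map <- function(map, x) {
  idx <- branch_index_of(map, x)
  pwl_assert(!anyNA(idx), "domain",
             sprintf("x outside the map domain [%g, %g)",
                     map$partition$lo, map$partition$hi))
  b <- map$branches
  y <- b$slope[idx] * x + b$intercept[idx]
  pmin(pmax(y, map$partition$lo), map$partition$hi)
}

#' Serialise / deserialise a map as JSON
#'
#' The JSON layout is `{domain: {lo, hi}, edges: [...], branches: [{x_lo,
#' x_hi, slope, intercept}, ...]}`. The reader re-runs full validation and
#' rejects files violating any map invariant.
#'
#' @param map a `pwl_map`.
#' @param path file path.
#' @export
write_map_json <- function(map, path) {
  obj <- list(domain = list(lo = map$partition$lo, hi = map$partition$hi),
              edges = map$partition$edges,
              branches = map$branches)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_map_json
#' @export
read_map_json <- function(path) {
  pwl_assert(file.exists(path), "io", sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pwl_assert(all(c("domain", "edges", "branches") %in% names(obj)),
             "schema", "map JSON needs fields domain, edges, branches")
  p <- partition(edges = obj$edges)
  pwl_assert(abs(p$lo - obj$domain$lo) <= 1e-12 && abs(p$hi - obj$domain$hi) <= 1e-12,
             "schema", "map JSON domain does not match its partition edges")
  pwl_map(p, as.data.frame(obj$branches))
}
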