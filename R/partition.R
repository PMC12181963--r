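#' Partition of the log10-intensity axis
#'
#' A partition is the ordered set of cell edges on which piecewise-constant
#' densities and the transfer operator live. All modelling happens on the
#' log10 fluorescence-intensity scale; the default domain `[0, 4]` covers
#' intensities from 10^0 to 10^4, the span of a typical 4-decade cytometer
#' axis.
#'
#' @param lo,hi domain bounds in log10-intensity units (decades).
#' @param n_cells number of cells for a uniform partition (ignored when
#'   `edges` is given).
#' @param edges optional explicit vector of cell edges, strictly increasing,
#'   length `n_cells + 1`.
#' @return an object of class `pwl_partition` with fields `edges`, `n`, `lo`,
#'   `hi`.
#' @examples
#' p <- partition(0, 4, 16)
#' cell_widths(p)
#' @export
partition <- function(lo = 0, hi = 4, n_cells = 16, edges = NULL) {
  if (is.null(edges)) {
    pwl_assert(is.numeric(lo) && is.numeric(hi) && lo < hi,
               "validation", "`lo` must be < `hi`")
    pwl_assert(n_cells >= 2, "validation", "a partition needs at least 2 cells")
    edges <- seq(lo, hi, length.out = n_cells + 1L)
    # guard against seq() rounding at the endpoints
    edges[1] <- lo
    edges[length(edges)] <- hi
  }
  edges <- as.numeric(edges)
  pwl_assert(length(edges) >= 3, "validation", "a partition needs at least 2 cells")
  pwl_assert(all(diff(edges) > 0), "validation", "partition edges must be strictly increasing")
  structure(
    list(edges = edges, n = length(edges) - 1L,
         lo = edges[1], hi = edges[length(edges)]),
    class = "pwl_partition")
}

#' @export
print.pwl_partition <- function(x, ...) {
  cat(sprintf("<pwl_partition> %d cells on [%g, %g] (log10 intensity)\n",
              x$n, x$lo, x$hi))
  invisible(x)
}

#' @rdname partition
#' @param p a `pwl_partition`.
#' @export
cell_widths <- function(p) diff(p$edges)

#' @rdname partition
#' @export
cell_centers <- function(p) (p$edges[-1] + p$edges[-length(p$edges)]) / 2

is_partition <- function(x) inherits(x, "pwl_partition")

same_partition <- function(a, b, tol = 0) {
  is_partition(a) && is_partition(b) && a$n == b$n &&
    (if (tol == 0) identical(a$edges, b$edges) else max(abs(a$edges - b$edges)) <= tol)
}

check_same_partition <- function(a, b) {
  pwl_assert(same_partition(a, b, tol = 1e-12), "incompatible",
             "objects live on different partitions")
}

# Index of the cell containing x under half-open cells [e_i, e_{i+1});
# x == hi is out of domain. Vectorised.
cell_index_of <- function(p, x) {
  idx <- findInterval(x, p$edges, rightmost.closed = FALSE)
  idx[x >= p$hi | x < p$lo] <- NA_integer_
  idx
}
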