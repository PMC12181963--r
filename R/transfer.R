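#' Transfer (Frobenius-Perron) matrices
#'
#' Restricted to piecewise-constant densities on a partition, the
#' Frobenius-Perron operator of a piecewise-linear map is a row-stochastic
#' matrix `Q`: `Q[i, j]` is the fraction of probability mass in cell `i`
#' transported to cell `j` in one step. This is the "Markov reading" of the
#' deterministic map.
#'
#' @param p a `pwl_partition`.
#' @param Q an `n x n` matrix with entries in `[0, 1]` and unit row sums
#'   (within 1e-6; rows are renormalised exactly).
#' @return a `pwl_transfer_matrix`.
#' @export
transfer_matrix <- function(p, Q) {
  pwl_assert(is_partition(p), "validation", "`p` must be a pwl_partition")
  Q <- as.matrix(Q)
  pwl_assert(nrow(Q) == p$n && ncol(Q) == p$n, "validation",
             sprintf("Q must be %d x %d", p$n, p$n))
  pwl_assert(all(is.finite(Q)) && all(Q >= -1e-12), "invalid_matrix",
             "Q entries must be finite and non-negative")
  Q[Q < 0] <- 0
  rs <- rowSums(Q)
  pwl_assert(all(abs(rs - 1) <= 1e-6), "invalid_matrix",
             sprintf("row sums deviate from 1 by up to %.3g", max(abs(rs - 1))))
  Q <- Q / rs
  dimnames(Q) <- NULL
  structure(list(partition = p, Q = Q), class = "pwl_transfer_matrix")
}

#' @export
print.pwl_transfer_matrix <- function(x, ...) {
  cat(sprintf("<pwl_transfer_matrix> %d x %d\n", x$partition$n, x$partition$n))
  print(signif(x$Q, 3))
  invisible(x)
}

#' Exact transfer matrix of a piecewise-linear map
#'
#' Computed from branch geometry, not by simulation: for each branch,
#' intersect its domain with cell `i`, push the sub-interval through the
#' affine branch, and apportion its Lebesgue measure over the target cells
#' its image crosses. `Q[i, j]` is that measure divided by the width of cell
#' `i`. Zero-width intersections contribute exactly 0.
#'
#' @param map a `pwl_map`.
#' @param p partition to discretise on; must equal the map's partition.
#' @return a `pwl_transfer_matrix`.
#' @export
transfer_matrix_of_map <- function(map, p = map$partition) {
  check_same_partition(map$partition, p)
  n <- p$n
  e <- p$edges
  w <- cell_widths(p)
  Q <- matrix(0, n, n)
  b <- map$branches
  for (k in seq_len(nrow(b))) {
    s <- b$slope[k]; c0 <- b$intercept[k]
    # cells overlapped by this branch's domain
    i_first <- max(1L, findInterval(b$x_lo[k], e, rightmost.closed = FALSE))
    i_last <- min(n, findInterval(b$x_hi[k], e, left.open = TRUE))
    for (i in i_first:i_last) {
      sub_lo <- max(b$x_lo[k], e[i])
      sub_hi <- min(b$x_hi[k], e[i + 1])
      if (sub_hi <= sub_lo) next
      if (s == 0) {
        # whole sub-interval collapses to one point
        y <- min(max(c0, p$lo), p$hi)
        j <- if (y >= p$hi) n else findInterval(y, e, rightmost.closed = FALSE)
        Q[i, j] <- Q[i, j] + (sub_hi - sub_lo) / w[i]
        next
      }
      ya <- s * sub_lo + c0
      yb <- s * sub_hi + c0
      img_lo <- max(min(ya, yb), p$lo)
      img_hi <- min(max(ya, yb), p$hi)
      if (img_hi <= img_lo) next
      j_first <- max(1L, findInterval(img_lo, e, rightmost.closed = FALSE))
      j_last <- min(n, findInterval(img_hi, e, left.open = TRUE))
      for (j in j_first:j_last) {
        ov <- min(img_hi, e[j + 1]) - max(img_lo, e[j])
        if (ov > 0) Q[i, j] <- Q[i, j] + ov / abs(s) / w[i]
      }
    }
  }
  rs <- rowSums(Q)
  pwl_assert(all(abs(rs - 1) <= 1e-9), "invalid_map",
             sprintf("map loses mass: row sums deviate by up to %.3g (image escaping the domain?)",
                     max(abs(rs - 1))))
  transfer_matrix(p, Q)
}

#' Evolve a density one step forward
#'
#' The transfer operator acts on mass vectors: `m'[j] = sum_i m[i] Q[i, j]`,
#' then heights are recovered as `m'[j] / width[j]`. Mass is conserved
#' because `Q` is row-stochastic.
#'
#' @param Qm a `pwl_transfer_matrix`.
#' @param f a `pwl_density` on the same partition.
#' @return a `pwl_density`.
#' @export
evolve_density <- function(Qm, f) {
  pwl_assert(inherits(Qm, "pwl_transfer_matrix"), "validation",
             "`Qm` must be a pwl_transfer_matrix")
  pwl_assert(inherits(f, "pwl_density"), "validation", "`f` must be a pwl_density")
  check_same_partition(Qm$partition, f$partition)
  m <- mass_of(f)
  m2 <- as.numeric(crossprod(Qm$Q, m))   # t(Q) %*% m
  density_from_mass(Qm$partition, m2)
}

#' Invariant density by power iteration
#'
#' Iterates the transfer operator from the uniform density until the L1
#' change per step is below `tol`. Power iteration (rather than a general
#' eigensolver) guarantees the result is a non-negative, normalised density.
#' Periodic chains that never settle (e.g. a permutation matrix started off
#' a fixed point) raise a convergence error reporting the final residual.
#'
#' @param Qm a `pwl_transfer_matrix`.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap.
#' @param init optional starting `pwl_density` (default: uniform).
#' @return a `pwl_density` `f*` with `l1_distance(evolve_density(Qm, f*), f*) <= tol`.
#' @export
invariant_density <- function(Qm, tol = 1e-10, max_iter = 10000L, init = NULL) {
  pwl_assert(is.numeric(tol) && tol > 0, "validation", "`tol` must be > 0")
  f <- init %||% uniform_density(Qm$partition)
  check_same_partition(Qm$partition, f$partition)
  for (it in seq_len(max_iter)) {
    f2 <- evolve_density(Qm, f)
    res <- l1_distance(f2, f)
    if (res <= tol) return(f2)
    f <- f2
  }
  pwl_stop("convergence",
           sprintf("power iteration did not converge in %d steps (final L1 residual %.3g)",
                   max_iter, res),
           residual = res)
}
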