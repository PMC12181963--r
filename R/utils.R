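#' @useDynLib pwlmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp setNames pnorm
#' @importFrom utils read.csv write.csv head tail
NULL

# Classed error helper: every pwlmap error carries class
# c("pwlmap_<what>", "pwlmap_error", "error", "condition") so callers and
# tests can dispatch on the failure kind rather than on message text.
pwl_stop <- function(what, msg, ...) {
  extra <- list(...)
  cond <- errorCondition(msg,
                         class = c(paste0("pwlmap_", what), "pwlmap_error"))
  for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  stop(cond)
}

pwl_assert <- function(ok, what, msg, ...) {
  if (!isTRUE(ok)) pwl_stop(what, msg, ...)
  invisible(TRUE)
}

# Derive a per-stream 32-bit seed from a master seed. `stream` is a small
# non-negative integer (e.g. a day index); the multiplier keeps streams with
# nearby master seeds well separated while staying below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
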