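#' Evaluate an expression under a local random seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library internals never perturb user-level streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic child seed derived from a master seed by a fixed stage offset.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(master_seed, offset) {
  (as.numeric(master_seed) * 131L + as.numeric(offset)) %% 2147483647
}

#' Geometric mean with pseudocount
#'
#' @param x non-negative numeric vector.
#' @param pseudocount added to every value before taking logs.
#' @return scalar geometric mean of `x + pseudocount`.
#' @keywords internal
geometric_mean <- function(x, pseudocount = 0) {
  exp(mean(log(x + pseudocount)))
}

# Population (divide-by-n) standard deviation.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
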