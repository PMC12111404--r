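# internal validation helpers

stop_if_not_scalar_number <- function(x, name, allow_zero = TRUE, allow_negative = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (!allow_negative && x < 0) {
    stop(sprintf("'%s' must be non-negative (got %g)", name, x), call. = FALSE)
  }
  if (!allow_zero && x == 0) {
    stop(sprintf("'%s' must be nonzero", name), call. = FALSE)
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), as used when
#' printed whole-percent ratios are compared with recomputed ones. Base R's
#' `round()` rounds half to even, which disagrees on exact .5 cases.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a child seed from a master seed and counters
#'
#' Every stochastic stage takes an explicit integer seed. Stages that need
#' several independent streams (topology repeats, restart batches) derive
#' child seeds deterministically from one master seed and a small set of
#' integer counters, so any sub-run can be reproduced standalone.
#'
#' The derivation is a multiplicative congruential mix modulo 2^31 - 1; the
#' result is always a positive integer below 2^31.
#'
#' @param seed master seed (single integer).
#' @param ... integer counters identifying the sub-stream (stage index,
#'   repeat index, init index, ...).
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stop_if_not_scalar_number(seed, "seed")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- (abs(seed) %% m)
  for (k in c(...)) {
    stop_if_not_scalar_number(k, "counter")
    x <- (x * 69069 + abs(k) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}
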