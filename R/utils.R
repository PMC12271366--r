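#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Round half away from zero
#'
#' Plain `round()` in R rounds half to even; intensity requantization here
#' uses the commutative half-away-from-zero rule instead so that endpoints
#' and midpoints map predictably.
#'
#' @param x numeric vector or matrix.
#' @return `x` rounded to integers (as numeric).
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Derive a per-item 31-bit seed stream from a base seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}

## Trapezoid quadrature on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

is_binary <- function(m) all(m %in% c(0, 1))

## Population (n-denominator) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
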