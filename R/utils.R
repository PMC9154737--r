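#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); published
#' trial tables round half up. `round_half_up(0.05, 1)` is 0.1, not 0.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# draw from Normal(mean, sd) truncated to [lo, hi] by inverse-CDF; vectorised,
# deterministic given the RNG state
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
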