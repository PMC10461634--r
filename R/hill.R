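#' Hill function
#'
#' Shared saturating dose-response primitive used throughout the secretion
#' model: for the net beta- and alpha-cell secretion rates, for the
#' hormone-hormone interaction terms, and for the glucose-dependent pool
#' transfer coefficients.
#'
#' Evaluated in log space, `m / (1 + exp(n * (log(h) - log(x))))`, so that
#' large exponents (the pool kinetics use n close to 10) do not overflow
#' for large signals.
#'
#' @param x Non-negative input signal (vectorized).
#' @param m Maximum of the response (plateau as `x -> Inf`).
#' @param h Half-saturation point; must be positive.
#' @param n Hill exponent; must be positive.
#'
#' @return `m * x^n / (x^n + h^n)`; 0 at `x = 0`.
#'
#' @examples
#' hill(3.97, m = 103, h = 3.97, n = 4.84) # half-maximal: 51.5
#' @export
hill <- function(x, m, h, n) {
  if (any(h <= 0) || any(n <= 0)) {
    stop("hill() requires h > 0 and n > 0", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("hill() requires non-negative x; signals are non-negative by construction",
         call. = FALSE)
  }
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- m / (1 + exp(n * (log(h) - log(x[pos]))))
  out
}
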