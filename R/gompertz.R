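#' Gompertz lifespan sampler
#'
#' Draws lifetimes from the Gompertz mortality law with hazard
#' \eqn{h(t) = a e^{bt}} and survival
#' \eqn{S(t) = \exp\{-(a/b)(e^{bt} - 1)\}}, the standard demographic model for
#' adult fly cohorts. Sampling is by inversion of the closed-form CDF, so the
#' draws are exact (no rejection step) and reproducible under a seed.
#'
#' @param n number of draws.
#' @param a initial hazard per day (> 0).
#' @param b hazard doubling-rate parameter per day. `b = 0` degenerates to the
#'   exponential law with rate `a`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return numeric vector of `n` lifetimes in days.
#' @examples
#' x <- rgompertz(5, a = 8e-4, b = 0.1, seed = 1)
#' @export
rgompertz <- function(n, a, b, seed = NULL) {
  n <- check_count(n, "n", min = 0L)
  a <- check_number(a, "a", min = 0, strict_min = TRUE)
  b <- check_number(b, "b", min = 0)
  u <- with_seed(seed, stats::runif(n))
  if (b == 0) return(-log1p(-u) / a)
  # F(t) = 1 - exp(-(a/b)(e^{bt}-1))  =>  t = log1p(-(b/a) log(1-u)) / b
  log1p(-(b / a) * log1p(-u)) / b
}

#' Gompertz survival function
#'
#' Closed-form survivor function \eqn{S(t) = \exp\{-(a/b)(e^{bt}-1)\}} used by
#' the lifespan generator and handy for checking simulated cohorts.
#'
#' @param t times in days (vector).
#' @inheritParams rgompertz
#' @return survival probabilities at `t`.
#' @export
gompertz_survival <- function(t, a, b) {
  a <- check_number(a, "a", min = 0, strict_min = TRUE)
  b <- check_number(b, "b", min = 0)
  if (b == 0) return(exp(-a * t))
  exp(-(a / b) * expm1(b * t))
}
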