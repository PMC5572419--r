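#' Lognormal impulse-response component
#'
#' One neuromuscular command in the sigma-lognormal model: a velocity lobe
#' `D * Lambda(t; t0, mu, sigma)` where `Lambda` is the shifted lognormal
#' density. `D` is the command amplitude (degrees: the area under the
#' velocity lobe), `t0` the command time (s), `mu` the log time delay and
#' `sigma` the log response time. Derived quantities:
#' `tbar = t0 + exp(mu + sigma^2/2)` (first moment of the impulse response),
#' `s_resp = (tbar - t0) * sqrt(exp(sigma^2) - 1)` (its standard deviation),
#' and `vmax = D * exp(-mu + sigma^2/2) / (sigma * sqrt(2*pi))` (peak
#' velocity, reached at `t0 + exp(mu - sigma^2)`).
#'
#' @param D command amplitude (degrees), `D > 0`.
#' @param t0 command time (s).
#' @param mu log time delay (log-seconds).
#' @param sigma log response time, `sigma > 0`.
#' @return a `lognormal_component` list with fields `D, t0, mu, sigma` and
#'   derived `tbar, s_resp, vmax`.
#' @export
lognormal_component <- function(D, t0, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive number", call. = FALSE)
  }
  if (!is.finite(D) || D <= 0) stop("D must be positive", call. = FALSE)
  tbar <- t0 + exp(mu + 0.5 * sigma^2)
  structure(
    list(D = D, t0 = t0, mu = mu, sigma = sigma,
         tbar = tbar,
         s_resp = (tbar - t0) * sqrt(exp(sigma^2) - 1),
         vmax = D * exp(-mu + 0.5 * sigma^2) / (sigma * sqrt(2 * pi))),
    class = "lognormal_component"
  )
}

#' @export
print.lognormal_component <- function(x, ...) {
  cat(sprintf(
    "<lognormal component: D = %.2f deg, t0 = %.3f s, mu = %.3f, sigma = %.3f>\n",
    x$D, x$t0, x$mu, x$sigma))
  cat(sprintf("  tbar = %.3f s, s = %.3f s, vmax = %.2f deg/s\n",
              x$tbar, x$s_resp, x$vmax))
  invisible(x)
}

#' Evaluate a lognormal velocity lobe
#'
#' `D * Lambda(t; t0, mu, sigma)` with
#' `Lambda(t) = 1 / (sigma (t - t0) sqrt(2*pi)) * exp(-(ln(t - t0) - mu)^2 / (2 sigma^2))`
#' for `t > t0` and 0 otherwise.
#'
#' @param t times (s), any numeric vector.
#' @param component a [lognormal_component()], or `D, t0, mu, sigma` given
#'   separately.
#' @param D,t0,mu,sigma scalar parameters, used when `component` is missing.
#' @return velocity values (deg/s), same length as `t`.
#' @export
lognormal_value <- function(t, component = NULL, D = NULL, t0 = NULL,
                            mu = NULL, sigma = NULL) {
  if (!is.null(component)) {
    D <- component$D; t0 <- component$t0
    mu <- component$mu; sigma <- component$sigma
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive number", call. = FALSE)
  }
  out <- numeric(length(t))
  ok <- t > t0
  tt <- t[ok] - t0
  out[ok] <- D / (sigma * tt * sqrt(2 * pi)) *
    exp(-(log(tt) - mu)^2 / (2 * sigma^2))
  out
}

#' Derived timing metrics of a component
#'
#' Closed forms of the impulse-response first moment and spread:
#' `tbar = t0 + exp(mu + 0.5 sigma^2)` and
#' `s_resp = (tbar - t0) * sqrt(exp(sigma^2) - 1)`.
#'
#' @param component a [lognormal_component()].
#' @return named numeric `c(tbar =, s_resp =)` in seconds.
#' @export
derived_timing <- function(component) {
  c(tbar = component$tbar, s_resp = component$s_resp)
}

#' Reconstruction signal-to-noise ratio
#'
#' `SNR = 10 log10( integral(v^2) / integral((v - v_hat)^2) )` with
#' trapezoidal integration over the common time grid, i.e. 20 log10 of the
#' L2-norm ratio. Perfect reconstructions are capped at +100 dB.
#'
#' @param v measured velocity profile.
#' @param v_hat reconstructed profile, same length.
#' @param t time grid (s).
#' @return SNR in dB.
#' @export
snr <- function(v, v_hat, t) {
  stopifnot(length(v) == length(v_hat), length(v) == length(t))
  num <- trapz(t, v^2)
  if (num <= 0) stop("zero-signal input: SNR undefined", call. = FALSE)
  den <- trapz(t, (v - v_hat)^2)
  if (den <= num * 1e-10) return(100)
  min(10 * log10(num / den), 100)
}

trapz <- function(t, y) {
  n <- length(y)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}
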