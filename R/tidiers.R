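#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-phase sigma-lognormal fit
#'
#' @param x an `sl_fit` from [fit_two_phase()].
#' @param ... unused.
#' @return a tibble with one row per phase and columns `phase, D, t0, mu,
#'   sigma, tbar, s_resp, vmax`.
#' @export
tidy.sl_fit <- function(x, ...) {
  row <- function(comp, phase) {
    if (is.null(comp)) {
      return(tibble::tibble(phase = phase, D = NA_real_, t0 = NA_real_,
                            mu = NA_real_, sigma = NA_real_, tbar = NA_real_,
                            s_resp = NA_real_, vmax = NA_real_))
    }
    tibble::tibble(phase = phase, D = comp$D, t0 = comp$t0, mu = comp$mu,
                   sigma = comp$sigma, tbar = comp$tbar,
                   s_resp = comp$s_resp, vmax = comp$vmax)
  }
  dplyr::bind_rows(row(x$phase1, 1L), row(x$phase2, 2L))
}

#' Glance at a two-phase sigma-lognormal fit
#'
#' @param x an `sl_fit`.
#' @param ... unused.
#' @return a one-row tibble: `snr_db, qc_pass, failed, method, n_samples,
#'   direction`.
#' @export
glance.sl_fit <- function(x, ...) {
  tibble::tibble(snr_db = x$snr_db, qc_pass = x$qc_pass, failed = x$failed,
                 method = x$method, n_samples = length(x$time_grid),
                 direction = x$direction)
}
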