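#' Plot a two-phase sigma-lognormal fit
#'
#' Measured vs reconstructed axial velocity profile, with the two lognormal
#' phases drawn individually (phase 2 negated, as it enters the model).
#'
#' @param object an `sl_fit` from [fit_two_phase()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sl_fit <- function(object, ...) {
  df <- tibble::tibble(t = object$time_grid, measured = object$v_measured)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$measured,
                                    colour = "measured")) +
    ggplot2::labs(x = "time (s)", y = "axial velocity (deg/s)",
                  colour = NULL,
                  subtitle = if (object$failed) {
                    paste("fit failed:", object$failure_reason)
                  } else {
                    sprintf("SNR = %.1f dB", object$snr_db)
                  })
  if (!is.null(object$v_reconstructed)) {
    df$reconstructed <- object$v_reconstructed
    df$phase1 <- lognormal_value(df$t, object$phase1)
    df$phase2 <- -lognormal_value(df$t, object$phase2)
    p <- p +
      ggplot2::geom_line(data = df,
                         ggplot2::aes(y = .data$reconstructed,
                                      colour = "reconstructed"),
                         linetype = "dashed") +
      ggplot2::geom_line(data = df,
                         ggplot2::aes(y = .data$phase1, colour = "phase 1"),
                         alpha = 0.6) +
      ggplot2::geom_line(data = df,
                         ggplot2::aes(y = .data$phase2, colour = "phase 2"),
                         alpha = 0.6)
  }
  p
}

#' Plot a reliability report
#'
#' ICC point estimates with 95% confidence intervals per metric, with the
#' interpretation bands shaded.
#'
#' @param report tibble from [reliability_report()].
#' @return a ggplot object.
#' @export
plot_reliability <- function(report) {
  bands <- tibble::tibble(lo = c(-Inf, 0.5, 0.75, 0.9),
                          hi = c(0.5, 0.75, 0.9, 1),
                          band = factor(c("poor", "moderate", "good",
                                          "excellent"),
                                        levels = c("poor", "moderate",
                                                   "good", "excellent")))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$metric, y = .data$icc)) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lo,
                                    ymax = .data$hi, fill = .data$band),
                       inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::coord_flip(ylim = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "ICC(A,k)", fill = NULL)
}
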