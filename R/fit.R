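#' Characteristic points of a single velocity lobe
#'
#' Locates the five characteristic points used for closed-form parameter
#' extraction: motion onset `tP1`, first inflection `tP2`, velocity peak
#' `tP3` (with value `vP3`), second inflection `tP4` and motion offset
#' `tP5`. The peak is refined by parabolic interpolation around the discrete
#' maximum; the inflections come from sign changes of the (lightly smoothed)
#' second difference, linearly interpolated; onset and offset are the first
#' and last crossings of `f_onset * vP3` and `f_offset * vP3`, walking
#' outward from the peak.
#'
#' @param v single positive velocity lobe (deg/s).
#' @param t time grid (s), uniform.
#' @param f_onset,f_offset onset/offset fractions of the peak (default 1%).
#' @param smooth smooth the second difference with a 5-sample moving average.
#' @return a `characteristic_points` list: `tP1, tP2, tP3, tP4, tP5, vP3`.
#' @export
find_characteristic_points <- function(v, t, f_onset = 0.01,
                                       f_offset = f_onset, smooth = TRUE) {
  if (length(v) < 10L) {
    extraction_error("lobe has fewer than 10 samples")
  }
  i3 <- which.max(v)
  if (i3 <= 1L || i3 >= length(v) || v[i3] <= 0) {
    extraction_error("no interior velocity maximum (monotone or empty lobe)")
  }
  peaks <- which(diff(sign(diff(v))) == -2) + 1L
  if (sum(v[peaks] > 0.5 * v[i3]) > 1L) {
    warning("multiple local maxima above 50% of peak; using the global maximum",
            call. = FALSE)
  }
  y1 <- v[i3 - 1L]; y2 <- v[i3]; y3 <- v[i3 + 1L]
  h <- t[i3 + 1L] - t[i3]
  den <- y1 - 2 * y2 + y3
  d <- if (den < 0) (y1 - y3) / (2 * den) else 0
  tP3 <- t[i3] + d * h
  vP3 <- y2 - 0.25 * (y1 - y3) * d
  d2 <- diff(v, differences = 2L)
  if (smooth) d2 <- as.numeric(stats::filter(d2, rep(0.2, 5L), sides = 2L))
  td2 <- t[2:(length(v) - 1L)]
  zero_cross <- function(idx, take_last) {
    s <- d2[idx]; ti <- td2[idx]
    ok <- which(!is.na(s[-1L]) & !is.na(s[-length(s)]) &
                  s[-1L] * s[-length(s)] < 0)
    if (!length(ok)) return(NA_real_)
    j <- if (take_last) ok[length(ok)] else ok[1L]
    ti[j] + abs(s[j]) / (abs(s[j]) + abs(s[j + 1L])) * (ti[j + 1L] - ti[j])
  }
  li <- which(td2 < tP3)
  ri <- which(td2 > tP3)
  tP2 <- if (length(li) >= 2L) zero_cross(li, TRUE) else NA_real_
  tP4 <- if (length(ri) >= 2L) zero_cross(ri, FALSE) else NA_real_
  if (is.na(tP2) || is.na(tP4)) {
    extraction_error("no inflection point found on one side of the peak")
  }
  lev1 <- f_onset * vP3
  i <- i3
  while (i > 1L && v[i - 1L] >= lev1) i <- i - 1L
  tP1 <- if (i == 1L) NA_real_ else {
    t[i - 1L] + (lev1 - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
  }
  lev5 <- f_offset * vP3
  i <- i3
  while (i < length(v) && v[i + 1L] >= lev5) i <- i + 1L
  tP5 <- if (i == length(v)) NA_real_ else {
    t[i] + (v[i] - lev5) / (v[i] - v[i + 1L]) * (t[i + 1L] - t[i])
  }
  if (is.na(tP1) || is.na(tP5)) {
    extraction_error("velocity does not fall to the onset/offset level within the lobe")
  }
  structure(list(tP1 = tP1, tP2 = tP2, tP3 = tP3, tP4 = tP4, tP5 = tP5,
                 vP3 = vP3),
            class = "characteristic_points")
}

extraction_error <- function(msg) {
  rlang::abort(msg, class = "turnsig_extraction_error")
}

# ratio of characteristic-point spacings as a function of sigma; this presumes
# onset/offset located at log-times mu -+ 3 sigma and the peak at mu - sigma^2
sigma_ratio_rhs <- function(s) {
  (exp(-s^2) - exp(-3 * s)) / (exp(3 * s) - exp(-3 * s))
}

#' Log response time from characteristic points
#'
#' Inverts the spacing identity
#' `(tP3 - tP1) / (tP5 - tP1) = (e^(-sigma^2) - e^(-3 sigma)) / (e^(3 sigma) - e^(-3 sigma))`
#' for `sigma` by bracketed root finding on `[0.01, 3]`.
#'
#' @param points a `characteristic_points` list.
#' @param clamp clamp an out-of-range ratio to the bracket instead of
#'   failing (used internally during iterative refinement).
#' @return the estimated `sigma`.
#' @export
estimate_sigma <- function(points, clamp = FALSE) {
  r <- (points$tP3 - points$tP1) / (points$tP5 - points$tP1)
  lo <- 0.01; hi <- 3
  r_lo <- sigma_ratio_rhs(hi)
  r_hi <- sigma_ratio_rhs(lo)
  if (r <= r_lo || r >= r_hi) {
    if (!clamp) {
      extraction_error(sprintf(
        "point-spacing ratio %.4f outside the invertible range (%.4f, %.4f)",
        r, r_lo, r_hi))
    }
    r <- min(max(r, r_lo + 1e-12), r_hi - 1e-12)
  }
  stats::uniroot(function(s) sigma_ratio_rhs(s) - r, c(lo, hi),
                 tol = 1e-10)$root
}

#' Remaining lognormal parameters from characteristic points
#'
#' Given `sigma`, the inflection spacing fixes the log time delay,
#' `mu = ln((tP4 - tP2) / (e^(-1.5 sigma^2 + w) - e^(-1.5 sigma^2 - w)))` with
#' `w = sigma * sqrt(0.25 sigma^2 + 1)`; the command time follows from the
#' peak location, `t0 = tP3 - e^(mu - sigma^2)`; and the amplitude from the
#' peak height, `D = sqrt(2*pi) * sigma * vP3 * e^(mu - sigma^2/2)`.
#' A self-consistency check verifies that the implied peak velocity matches
#' `vP3` within 0.5%.
#'
#' @param points a `characteristic_points` list.
#' @param sigma from [estimate_sigma()].
#' @return named numeric `c(mu =, t0 =, D =)`.
#' @export
estimate_mu_t0_D <- function(points, sigma) {
  if (points$tP4 <= points$tP2) {
    extraction_error("inflection points out of order")
  }
  w <- sigma * sqrt(0.25 * sigma^2 + 1)
  mu <- log((points$tP4 - points$tP2) /
              (exp(-1.5 * sigma^2 + w) - exp(-1.5 * sigma^2 - w)))
  t0 <- points$tP3 - exp(mu - sigma^2)
  D <- sqrt(2 * pi) * sigma * points$vP3 * exp(mu - sigma^2 / 2)
  vpk <- D * exp(-mu + 0.5 * sigma^2) / (sigma * sqrt(2 * pi))
  if (abs(vpk - points$vP3) > 0.005 * points$vP3) {
    extraction_error("peak-height consistency check failed")
  }
  c(mu = mu, t0 = t0, D = D)
}

# --- internal single-lobe estimation --------------------------------------

# spline-upsample a lobe so sub-sample geometry is resolved
upsample_lobe <- function(v, t, hz = 600) {
  dt <- t[2] - t[1]
  if (dt <= 1 / hz + 1e-12) return(list(v = v, t = t))
  tf <- seq(t[1], t[length(t)], by = 1 / hz)
  list(v = stats::spline(t, v, xout = tf)$y, t = tf)
}

# full estimate of one lobe: the onset/offset fractions the spacing identity
# presumes depend on sigma (velocity at log-time mu -+ 3 sigma is
# exp(-(sigma -+ 3)^2 / 2) of the peak), so the crossings are recalibrated
# until sigma is self-consistent
estimate_component_core <- function(v, t, fraction = 0.01, max_iter = 10L) {
  up <- upsample_lobe(v, t)
  v <- up$v; t <- up$t
  f1 <- fraction; f5 <- fraction
  est <- NULL; s_prev <- Inf
  for (k in seq_len(max_iter)) {
    p <- suppressWarnings(find_characteristic_points(v, t, f1, f5))
    s <- estimate_sigma(p, clamp = TRUE)
    r <- estimate_mu_t0_D_noncheck(p, s)
    est <- c(sigma = s, r)
    if (anyNA(est)) extraction_error("non-finite parameter estimate")
    if (abs(s - s_prev) < 1e-9) break
    s_prev <- s
    f1 <- exp(-(s - 3)^2 / 2)
    f5 <- exp(-(s + 3)^2 / 2)
  }
  est
}

# as estimate_mu_t0_D but without the 0.5% consistency gate (iterations pass
# through intermediate states that need not be consistent yet)
estimate_mu_t0_D_noncheck <- function(points, sigma) {
  if (points$tP4 <= points$tP2) extraction_error("inflection points out of order")
  w <- sigma * sqrt(0.25 * sigma^2 + 1)
  mu <- log((points$tP4 - points$tP2) /
              (exp(-1.5 * sigma^2 + w) - exp(-1.5 * sigma^2 - w)))
  t0 <- points$tP3 - exp(mu - sigma^2)
  D <- sqrt(2 * pi) * sigma * points$vP3 * exp(mu - sigma^2 / 2)
  c(mu = mu, t0 = t0, D = D)
}

# one-sided initial estimate using only the uncontaminated flank of a lobe:
# onset side (tP1, tP2, tP3) for the leading lobe, offset side (tP3, tP4, tP5)
# for the trailing one; solves the three point-location identities for
# (sigma, t0), then mu and D
estimate_oneside <- function(v, t, side = c("onset", "offset"),
                             fraction = 0.01) {
  side <- match.arg(side)
  up <- upsample_lobe(v, t)
  v <- up$v; t <- up$t
  p <- suppressWarnings(find_characteristic_points(v, t, fraction, fraction))
  a <- sqrt(2 * log(1 / fraction))
  g32 <- function(s) 0.5 * s^2 + s * sqrt(0.25 * s^2 + 1)
  g34 <- function(s) -0.5 * s^2 + s * sqrt(0.25 * s^2 + 1)
  inv_monotone <- function(g, r, lo = 1e-6, hi = 5) {
    r <- min(max(r, g(lo) + 1e-12), g(hi) - 1e-12)
    stats::uniroot(function(s) g(s) - r, c(lo, hi), tol = 1e-10)$root
  }
  if (side == "onset") {
    anchor <- p$tP1
    mismatch <- function(t0) {
      log((p$tP3 - t0) / (p$tP1 - t0)) / a -
        inv_monotone(g32, log((p$tP3 - t0) / (p$tP2 - t0)))
    }
  } else {
    anchor <- p$tP3
    mismatch <- function(t0) {
      log((p$tP5 - t0) / (p$tP3 - t0)) / a -
        inv_monotone(g34, log((p$tP4 - t0) / (p$tP3 - t0)))
    }
  }
  cand <- anchor - exp(seq(log(1e-4), log(50), length.out = 80L))
  hv <- vapply(cand, function(z) {
    tryCatch(mismatch(z), error = function(e) NA_real_)
  }, numeric(1))
  j <- which(!is.na(hv[-1L]) & !is.na(hv[-length(hv)]) &
               hv[-1L] * hv[-length(hv)] <= 0)
  if (!length(j)) extraction_error("one-sided initialization found no root")
  t0 <- stats::uniroot(mismatch, c(cand[j[1L] + 1L], cand[j[1L]]),
                       tol = 1e-10)$root
  s <- if (side == "onset") log((p$tP3 - t0) / (p$tP1 - t0)) / a else
    log((p$tP5 - t0) / (p$tP3 - t0)) / a
  mu <- log(p$tP3 - t0) + s^2
  D <- sqrt(2 * pi) * s * p$vP3 * exp(mu - s^2 / 2)
  est <- c(sigma = s, mu = mu, t0 = t0, D = D)
  if (anyNA(est)) extraction_error("non-finite one-sided estimate")
  est
}

lobe_value <- function(t, p) {
  lognormal_value(t, D = p[["D"]], t0 = p[["t0"]], mu = p[["mu"]],
                  sigma = p[["sigma"]])
}

#' Two-phase sigma-lognormal fit of an axial velocity profile
#'
#' Decomposes the relative head-to-trunk axial angular-velocity profile of a
#' turn into two lognormal phases,
#' `v(t) = D1 Lambda(t; t01, mu1, sigma1) - D2 Lambda(t; t02, mu2, sigma2)`:
#' the head-leads lobe (positive) and the trunk-catches-up lobe (negative).
#' Input direction is normalized so the first lobe is positive; left and
#' right turns fit identically.
#'
#' Each phase is first estimated from its characteristic points, using only
#' the uncontaminated flank of each lobe for initialization (the onset flank
#' of phase 1 and the offset flank of phase 2), then refined by alternating
#' lobe subtraction (re-extracting points on `v + D2 Lambda2` and
#' `D1 Lambda1 - v`), keeping the iterate with the best reconstruction SNR.
#' With `refine = TRUE` (default) the eight parameters are polished by
#' Levenberg-Marquardt least squares on the reconstruction residual; the
#' polish is kept only when it improves the SNR.
#'
#' @param v axial angular velocity over the turn segment (deg/s).
#' @param t time grid (s), uniform sampling.
#' @param fraction initial onset/offset fraction of peak (default 1%).
#' @param refine polish with nonlinear least squares (default TRUE).
#' @param snr_gate_db quality gate applied to the reconstruction (dB).
#' @param warm_starts number of alternating-subtraction passes.
#' @param lobe_tol a second lobe must reach this fraction of the first
#'   lobe's peak to count as detected.
#' @return an `sl_fit` object: components `phase1` and `phase2`
#'   ([lognormal_component()]), `time_grid`, `v_measured` (after direction
#'   normalization), `v_reconstructed`, `snr_db`, `qc_pass`, `failed`,
#'   `failure_reason`, `direction` (+1/-1 applied to the input) and `method`.
#' @export
fit_two_phase <- function(v, t, fraction = 0.01, refine = TRUE,
                          snr_gate_db = 10, warm_starts = 4L,
                          lobe_tol = 0.05) {
  stopifnot(length(v) == length(t), length(v) >= 20L)
  dir <- turn_direction(v)
  v <- dir * v
  failed_fit <- function(reason, p1 = NULL, p2 = NULL) {
    structure(
      list(phase1 = if (!is.null(p1)) as_component(p1),
           phase2 = if (!is.null(p2)) as_component(p2),
           time_grid = t, v_measured = v, v_reconstructed = NULL,
           snr_db = NA_real_, qc_pass = FALSE, failed = TRUE,
           failure_reason = reason, direction = dir, method = "points"),
      class = "sl_fit")
  }
  vmax <- max(v); vmin <- min(v)
  if (vmax <= 0 || -vmin < lobe_tol * vmax) {
    p1 <- tryCatch(estimate_component_core(pmax(v, 0), t, fraction),
                   error = function(e) NULL)
    return(failed_fit("fewer than two lobes detected", p1 = p1))
  }
  if (which.max(v) > which.min(v)) {
    return(failed_fit("negative lobe precedes positive lobe after normalization"))
  }
  try_est <- function(expr) tryCatch(expr, error = function(e) NULL)
  # one-sided initialization is most accurate on clean overlapping lobes;
  # the plain full-lobe estimator is the fallback on noisy profiles
  p1 <- try_est(estimate_oneside(pmax(v, 0), t, "onset", fraction))
  if (is.null(p1)) p1 <- try_est(estimate_component_core(pmax(v, 0), t,
                                                         fraction))
  p2 <- try_est(estimate_oneside(pmax(-v, 0), t, "offset", fraction))
  if (is.null(p2)) p2 <- try_est(estimate_component_core(pmax(-v, 0), t,
                                                         fraction))
  if (is.null(p2) && !is.null(p1)) {
    p2 <- try_est(estimate_component_core(pmax(lobe_value(t, p1) - v, 0),
                                          t, fraction))
  }
  if (is.null(p1) && !is.null(p2)) {
    p1 <- try_est(estimate_component_core(pmax(v + lobe_value(t, p2), 0),
                                          t, fraction))
  }
  if (is.null(p1) || is.null(p2)) {
    return(failed_fit("phase initialization failed", p1 = p1, p2 = p2))
  }
  best <- list(p1 = p1, p2 = p2)
  best_snr <- -Inf
  consider <- function(p1, p2) {
    if (is.null(p1) || is.null(p2) || anyNA(c(p1, p2))) return(invisible())
    if (p1[["sigma"]] <= 0 || p2[["sigma"]] <= 0 ||
        p1[["D"]] <= 0 || p2[["D"]] <= 0) return(invisible())
    vhat <- lobe_value(t, p1) - lobe_value(t, p2)
    s <- snr(v, vhat, t)
    if (s > best_snr) {
      best_snr <<- s
      best <<- list(p1 = p1, p2 = p2)
    }
    invisible()
  }
  consider(p1, p2)
  for (k in seq_len(warm_starts)) {
    e1 <- tryCatch(
      estimate_component_core(pmax(v + lobe_value(t, p2), 0), t, fraction),
      error = function(e) NULL)
    if (is.null(e1)) break
    e2 <- tryCatch(
      estimate_component_core(pmax(lobe_value(t, e1) - v, 0), t, fraction),
      error = function(e) NULL)
    if (is.null(e2)) break
    p1 <- e1; p2 <- e2
    consider(p1, p2)
  }
  method <- "points"
  if (refine) {
    pol <- refine_lm(v, t, best$p1, best$p2)
    if (!is.null(pol)) {
      before <- best_snr
      consider(pol$p1, pol$p2)
      if (best_snr > before) method <- "points+ls"
    }
  }
  vhat <- lobe_value(t, best$p1) - lobe_value(t, best$p2)
  snr_db <- snr(v, vhat, t)
  structure(
    list(phase1 = as_component(best$p1), phase2 = as_component(best$p2),
         time_grid = t, v_measured = v, v_reconstructed = vhat,
         snr_db = snr_db, qc_pass = snr_db > snr_gate_db, failed = FALSE,
         failure_reason = NA_character_, direction = dir, method = method),
    class = "sl_fit")
}

as_component <- function(p) {
  lognormal_component(D = p[["D"]], t0 = p[["t0"]], mu = p[["mu"]],
                      sigma = p[["sigma"]])
}

# Levenberg-Marquardt polish of the 8 parameters (D and sigma through log
# transforms to stay positive)
refine_lm <- function(v, t, p1, p2) {
  par0 <- c(log(p1[["D"]]), p1[["t0"]], p1[["mu"]], log(p1[["sigma"]]),
            log(p2[["D"]]), p2[["t0"]], p2[["mu"]], log(p2[["sigma"]]))
  if (anyNA(par0)) return(NULL)
  resid_fn <- function(p) {
    lognormal_value(t, D = exp(p[1]), t0 = p[2], mu = p[3], sigma = exp(p[4])) -
      lognormal_value(t, D = exp(p[5]), t0 = p[6], mu = p[7],
                      sigma = exp(p[8])) - v
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- unname(fit$par)
  if (anyNA(p)) return(NULL)
  list(p1 = c(sigma = exp(p[4]), mu = p[3], t0 = p[2], D = exp(p[1])),
       p2 = c(sigma = exp(p[8]), mu = p[7], t0 = p[6], D = exp(p[5])))
}

#' @export
print.sl_fit <- function(x, ...) {
  if (x$failed) {
    cat("<sl_fit: FAILED -", x$failure_reason, ">\n")
    return(invisible(x))
  }
  cat(sprintf("<sl_fit: SNR = %.1f dB, qc %s, method %s>\n",
              x$snr_db, if (x$qc_pass) "pass" else "fail", x$method))
  cat(" phase 1 (head leads):  ")
  cat(sprintf("D = %.2f, t0 = %.3f, mu = %.3f, sigma = %.3f\n",
              x$phase1$D, x$phase1$t0, x$phase1$mu, x$phase1$sigma))
  cat(" phase 2 (trunk joins): ")
  cat(sprintf("D = %.2f, t0 = %.3f, mu = %.3f, sigma = %.3f\n",
              x$phase2$D, x$phase2$t0, x$phase2$mu, x$phase2$sigma))
  invisible(x)
}
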