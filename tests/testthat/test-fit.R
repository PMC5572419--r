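test_that("characteristic points locate peak, inflections and onset/offset", {
  t <- seq(0, 6, by = 1 / 600)
  v <- lobe_oracle(t, 25, 0, 0, 0.5)
  p <- find_characteristic_points(v, t)
  # closed-form locations for (t0 = 0, mu = 0, sigma = 0.5), numerically
  # verified by root-finding on the analytic curve
  expect_equal(p$tP3, exp(-0.25), tolerance = 1e-3 / exp(-0.25))
  w <- 0.5 * sqrt(0.25 * 0.25 + 1)
  expect_lt(abs(p$tP2 - exp(-0.375 - w)), 2e-3)
  expect_lt(abs(p$tP4 - exp(-0.375 + w)), 2e-3)
  expect_true(p$tP1 < p$tP2 && p$tP2 < p$tP3 && p$tP3 < p$tP4 &&
                p$tP4 < p$tP5)
  expect_equal(p$vP3, 25 * exp(0.125) / (0.5 * sqrt(2 * pi)),
               tolerance = 1e-4)

  # symmetric Gaussian lobe: peak centred, inflections symmetric
  g <- exp(-(t - 3)^2 / (2 * 0.4^2))
  pg <- find_characteristic_points(g, t)
  expect_equal(pg$tP3, 3, tolerance = 1e-6)
  expect_equal(pg$tP3 - pg$tP2, pg$tP4 - pg$tP3, tolerance = 1e-3)

  # monotone ramp has no interior maximum
  expect_error(find_characteristic_points(t, t),
               class = "turnsig_extraction_error")
  # bimodal lobe warns about ambiguity
  vv <- lobe_oracle(t, 25, 0, 0, 0.3) + lobe_oracle(t, 20, 2.2, 0, 0.3)
  expect_warning(find_characteristic_points(vv, t), "multiple local maxima")
})

test_that("sigma inversion reproduces the forward spacing identity", {
  # forward-evaluated points for sigma = 0.5 under the mu -+ 3 sigma
  # onset/offset convention: tP1 = e^-1.5, tP3 = e^-0.25, tP5 = e^1.5
  p <- structure(list(tP1 = exp(-1.5), tP2 = NA, tP3 = exp(-0.25),
                      tP4 = NA, tP5 = exp(1.5),
                      vP3 = exp(0.125) / (0.5 * sqrt(2 * pi))),
                 class = "characteristic_points")
  ratio <- (p$tP3 - p$tP1) / (p$tP5 - p$tP1)
  expect_equal(ratio, 0.13049, tolerance = 1e-4)
  expect_equal(estimate_sigma(p), 0.5, tolerance = 1e-6)

  # the spacing ratio is strictly monotone on the bracket: unique root
  s_grid <- seq(0.01, 3, length.out = 500)
  rhs <- (exp(-s_grid^2) - exp(-3 * s_grid)) /
    (exp(3 * s_grid) - exp(-3 * s_grid))
  expect_true(all(diff(rhs) < 0))

  # ratio outside the invertible range fails loudly
  p_bad <- p
  p_bad$tP5 <- p$tP3 + 1e-4
  expect_error(estimate_sigma(p_bad), class = "turnsig_extraction_error")
})

test_that("mu, t0, D follow from the remaining point identities", {
  # peak-height identity: sigma = 0.5, mu = 0, vP3 = 0.9041 implies D = 1
  vP3 <- exp(0.125) / (0.5 * sqrt(2 * pi))
  expect_equal(vP3, 0.9041, tolerance = 1e-4)
  w <- 0.5 * sqrt(0.25 * 0.25 + 1)
  p <- structure(list(tP1 = exp(-1.5), tP2 = exp(-0.375 - w),
                      tP3 = exp(-0.25), tP4 = exp(-0.375 + w),
                      tP5 = exp(1.5), vP3 = vP3),
                 class = "characteristic_points")
  est <- estimate_mu_t0_D(p, 0.5)
  expect_equal(unname(est["mu"]), 0, tolerance = 1e-9)
  expect_equal(unname(est["t0"]), 0.7788008 - exp(-0.25), tolerance = 1e-6)
  expect_equal(unname(est["D"]), 1, tolerance = 1e-9)

  # forward-simulate then invert at 600 Hz (with the self-consistent
  # onset/offset recalibration): (mu, t0, D) recovered
  t <- seq(0, 4, by = 1 / 600)
  v <- lobe_oracle(t, 25, 0.2, -0.1, 0.35)
  est2 <- turnsig:::estimate_component_core(v, t)
  expect_equal(unname(est2["mu"]), -0.1, tolerance = 0.005)
  expect_equal(unname(est2["t0"]), 0.2, tolerance = 5e-3)
  expect_equal(unname(est2["D"]), 25, tolerance = 25 * 0.005)

  p_bad <- p
  p_bad$tP4 <- p$tP2 - 0.01
  expect_error(estimate_mu_t0_D(p_bad, 0.5),
               class = "turnsig_extraction_error")
})

test_that("single components invert to high accuracy over the full range", {
  # property: forward-simulate noiseless at 240 Hz, invert via the
  # characteristic points; 50 draws here (the acceptance suite runs 200)
  set.seed(11)
  for (i in 1:50) {
    D <- runif(1, 5, 60); s <- runif(1, 0.1, 0.8)
    mu <- runif(1, -1.5, 0.5); t0 <- runif(1, 0, 1)
    t <- seq(0, t0 + exp(mu + 4 * s) + 0.5, by = 1 / 240)
    est <- turnsig:::estimate_component_core(lobe_oracle(t, D, t0, mu, s), t)
    expect_lt(abs(est[["sigma"]] - s) / s, 0.02)
    expect_lt(abs(est[["mu"]] - mu), 0.02)
    expect_lt(abs(est[["t0"]] - t0), 0.02)
    expect_lt(abs(est[["D"]] - D) / D, 0.02)
  }
})

test_that("two-phase decomposition recovers both commands at 60 Hz", {
  t <- seq(0, 6, by = 1 / 60)
  v <- lobe_oracle(t, 25, 0, 0, 0.3) - lobe_oracle(t, 25, 0.4, 0.2, 0.3)
  fit <- fit_two_phase(v, t)
  expect_false(fit$failed)
  expect_gte(fit$snr_db, 25)
  expect_equal(fit$phase1$D, 25, tolerance = 25 * 0.02)
  expect_equal(fit$phase2$D, 25, tolerance = 25 * 0.02)
  expect_equal(fit$phase1$sigma, 0.3, tolerance = 0.3 * 0.02)
  expect_equal(fit$phase2$sigma, 0.3, tolerance = 0.3 * 0.02)
  expect_equal(fit$phase1$mu, 0, tolerance = 0.02)
  expect_equal(fit$phase2$mu, 0.2, tolerance = 0.02)
  expect_equal(fit$phase1$t0, 0, tolerance = 0.02)
  expect_equal(fit$phase2$t0, 0.4, tolerance = 0.02)

  # reconstruction satisfies the model structure
  vhat <- lognormal_value(t, fit$phase1) - lognormal_value(t, fit$phase2)
  expect_equal(fit$v_reconstructed, vhat, tolerance = 1e-12)

  # mirror oracle: a left turn fits identically after normalization
  fit_l <- fit_two_phase(-v, t)
  expect_equal(fit_l$phase1$D, fit$phase1$D, tolerance = 1e-9)
  expect_equal(fit_l$direction, -fit$direction)

  # determinism: same input, bit-identical parameters
  fit2 <- fit_two_phase(v, t)
  expect_identical(tidy(fit), tidy(fit2))
})

test_that("degenerate profiles are flagged, with partial results kept", {
  t <- seq(0, 6, by = 1 / 60)
  v1 <- lobe_oracle(t, 25, 0.2, -0.2, 0.3)
  fit <- fit_two_phase(v1, t)
  expect_true(fit$failed)
  expect_match(fit$failure_reason, "two lobes")
  expect_false(fit$qc_pass)
  # the single visible lobe is still characterized
  expect_equal(fit$phase1$D, 25, tolerance = 25 * 0.02)

  g <- glance(fit)
  expect_true(g$failed)
  expect_true(is.na(g$snr_db))
})

test_that("realigned turns have matching command amplitudes", {
  # integral of the profile is D1 - D2; realigned turns have D1 = D2
  t <- seq(0, 8, by = 1 / 60)
  v <- lobe_oracle(t, 30, 0.1, -0.35, 0.28) -
    lobe_oracle(t, 30, 0.85, -0.25, 0.24)
  fit <- fit_two_phase(v, t)
  expect_false(fit$failed)
  expect_lt(abs(fit$phase1$D - fit$phase2$D), 0.02 * fit$phase1$D)
  area <- trapz_oracle(t, fit$v_reconstructed)
  expect_equal(area, fit$phase1$D - fit$phase2$D, tolerance = 0.3)
})

test_that("tidy and glance expose the fitted parameters", {
  t <- seq(0, 6, by = 1 / 60)
  v <- lobe_oracle(t, 25, 0, 0, 0.3) - lobe_oracle(t, 25, 0.4, 0.2, 0.3)
  fit <- fit_two_phase(v, t)
  td <- tidy(fit)
  expect_equal(nrow(td), 2L)
  expect_named(td, c("phase", "D", "t0", "mu", "sigma", "tbar", "s_resp",
                     "vmax"))
  expect_equal(td$tbar, td$t0 + exp(td$mu + td$sigma^2 / 2),
               tolerance = 1e-12)
  g <- glance(fit)
  expect_true(g$qc_pass)
  expect_equal(g$n_samples, length(t))
})
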