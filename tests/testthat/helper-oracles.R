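# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# rotation matrix from a scalar-first quaternion (independent of quat_multiply)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# quaternion-derivative angular-velocity oracle: omega = vec(2 qdot (x) q*)
# with qdot from central differences, written out longhand
omega_qdot_oracle <- function(t, q) {
  n <- nrow(q)
  qd <- matrix(NA_real_, n, 4)
  for (j in 1:4) {
    qd[, j] <- c((q[2, j] - q[1, j]) / (t[2] - t[1]),
                 (q[3:n, j] - q[1:(n - 2), j]) / (t[3:n] - t[1:(n - 2)]),
                 (q[n, j] - q[n - 1, j]) / (t[n] - t[n - 1]))
  }
  ham <- function(a, b) c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  t(vapply(seq_len(n), function(i) {
    2 * ham(qd[i, ], c(q[i, 1], -q[i, 2:4]))[2:4]
  }, numeric(3)))
}

# shifted lognormal velocity lobe, written independently of the package
lobe_oracle <- function(t, D, t0, mu, sigma) {
  out <- numeric(length(t))
  ok <- t > t0
  out[ok] <- D * stats::dlnorm(t[ok] - t0, meanlog = mu, sdlog = sigma)
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-way ANOVA mean squares through stats::aov (independent of icc_2k)
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.numeric(m),
                   row = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (msc - mse) / n)
}

# trapezoidal integral, independent of the package's internals
trapz_oracle <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

# a small smooth wobble track used by several kinematics tests; a fixed
# roll bias keeps the total rotation angle away from zero, where the
# rotation axis is undefined
make_wobble_track <- function(fs = 600, dur = 2, amp = 0.4, segment = "head") {
  t <- seq(0, dur, by = 1 / fs)
  yaw <- amp * sin(2 * pi * 0.7 * t)
  pitch <- 0.5 * amp * sin(2 * pi * 0.5 * t + 0.3)
  qb <- c(cos(0.3), sin(0.3), 0, 0)
  qy <- cbind(cos(yaw / 2), 0, 0, sin(yaw / 2))
  qp <- cbind(cos(pitch / 2), 0, sin(pitch / 2), 0)
  q <- quat_multiply(matrix(qb, length(t), 4, byrow = TRUE),
                     quat_multiply(qy, qp))
  orientation_track(t, q, segment = segment, sampling_rate = fs)
}
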