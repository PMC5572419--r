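test_that("Hamilton product matches rotation-matrix composition", {
  idq <- c(1, 0, 0, 0)
  yaw90 <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  expect_equal(unname(quat_multiply(yaw90, idq)), yaw90)
  expect_equal(unname(quat_multiply(yaw90, quat_conjugate(yaw90))), idq,
               tolerance = 1e-12)
  # 90 yaw then 90 yaw = 180 yaw, checked against matrix composition
  q2 <- quat_multiply(yaw90, yaw90)
  expect_equal(quat_to_matrix(q2),
               quat_to_matrix(yaw90) %*% quat_to_matrix(yaw90),
               tolerance = 1e-12)
  expect_equal(unname(q2), c(cos(pi / 2), 0, 0, sin(pi / 2)),
               tolerance = 1e-12)
  # random unit quaternions: product matches matrix product
  set.seed(1)
  for (i in 1:20) {
    a <- quat_normalize(rnorm(4))[1, ]
    b <- quat_normalize(rnorm(4))[1, ]
    expect_equal(quat_to_matrix(quat_multiply(a, b)),
                 quat_to_matrix(a) %*% quat_to_matrix(b), tolerance = 1e-12)
  }
  expect_error(quat_multiply(c(NA, 0, 0, 1), idq), "non-finite")
})

test_that("alignment recovers the neutral-pose orientation", {
  t <- seq(0, 2, by = 1 / 60)
  q0 <- quat_normalize(c(0.9, 0.1, -0.2, 0.3))[1, ]
  tr <- orientation_track(t, matrix(q0, length(t), 4, byrow = TRUE))
  al <- compute_alignment(tr, c(0, 1))
  expect_equal(unname(al), unname(quat_conjugate(q0)), tolerance = 1e-12)
  aligned <- apply_alignment(tr, al)
  expect_equal(max(abs(as.matrix(aligned[, c("qx", "qy", "qz")]))), 0,
               tolerance = 1e-9)

  idt <- orientation_track(t, matrix(c(1, 0, 0, 0), length(t), 4,
                                     byrow = TRUE))
  expect_equal(unname(compute_alignment(idt, c(0, 1))), c(1, 0, 0, 0))

  # jitter of +-1 degree around q0: alignment within 0.5 degree of q0*
  set.seed(2)
  ang <- rnorm(length(t), 0, pi / 180 / 3)
  ax <- matrix(rnorm(3 * length(t)), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  qj <- quat_multiply(matrix(q0, length(t), 4, byrow = TRUE),
                      cbind(cos(ang / 2), sin(ang / 2) * ax))
  trj <- orientation_track(t, qj)
  alj <- compute_alignment(trj, c(0, 1))
  err <- quat_multiply(alj, q0)  # should be near identity
  expect_lt(2 * acos(min(abs(err[1]), 1)) * 180 / pi, 0.5)

  expect_error(compute_alignment(tr, c(10, 11)), "outside")
  # dispersed window triggers a warning but still returns
  qd <- rbind(matrix(q0, 40, 4, byrow = TRUE),
              matrix(quat_multiply(q0, c(cos(0.1), 0, 0, sin(0.1))),
                     81, 4, byrow = TRUE))
  trd <- orientation_track(t, qd)
  expect_warning(compute_alignment(trd, c(0, 1)), "dispersion")
})

test_that("relative orientation is the trunk-frame head rotation", {
  tr <- make_wobble_track(fs = 120, dur = 1)
  rel_self <- relative_orientation(tr, tr)
  expect_equal(max(abs(rel_self$qw - 1)), 0, tolerance = 1e-9)

  t <- seq(0, 1, by = 1 / 60)
  idt <- orientation_track(t, matrix(c(1, 0, 0, 0), length(t), 4,
                                     byrow = TRUE), "trunk")
  q30 <- c(cos(pi / 12), 0, 0, sin(pi / 12))
  head30 <- orientation_track(t, matrix(q30, length(t), 4, byrow = TRUE),
                              "head")
  rel <- relative_orientation(head30, idt)
  expect_equal(unname(as_quat_matrix(rel)[1, ]), q30, tolerance = 1e-12)

  # algebraic reconstruction: trunk (x) q_rel == head
  head_tr <- make_wobble_track(fs = 120, dur = 1, amp = 0.6, segment = "head")
  trunk_tr <- make_wobble_track(fs = 120, dur = 1, amp = 0.3,
                                segment = "trunk")
  rel2 <- relative_orientation(head_tr, trunk_tr)
  back <- quat_multiply(as_quat_matrix(trunk_tr), as_quat_matrix(rel2))
  dots <- abs(rowSums(back * as_quat_matrix(head_tr)))
  expect_equal(max(abs(dots - 1)), 0, tolerance = 1e-9)

  short <- orientation_track(t[-1], matrix(c(1, 0, 0, 0), length(t) - 1, 4,
                                           byrow = TRUE))
  expect_error(relative_orientation(head30, short), "time base")
})

test_that("axis-angle decomposition round-trips and handles identity", {
  t <- seq(0, 1, by = 1 / 60)
  idt <- orientation_track(t, matrix(c(1, 0, 0, 0), length(t), 4,
                                     byrow = TRUE))
  aa <- to_axis_angle(idt)
  expect_equal(max(aa$theta), 0)
  expect_equal(aa$uz[1], 1)  # axis convention at identity

  q15 <- matrix(c(cos(pi / 12), 0, 0, sin(pi / 12)), 12, 4, byrow = TRUE)
  aa15 <- to_axis_angle(orientation_track(seq(0, 11) / 60, q15))
  expect_equal(aa15$theta[1], pi / 6, tolerance = 1e-12)
  expect_equal(aa15$uz[1], 1, tolerance = 1e-12)

  # round trip over theta in (0, pi) about a common axis (consecutive
  # samples share a hemisphere, so construction applies no sign flips)
  set.seed(3)
  th <- runif(50, 0.01, pi - 0.01)
  ax0 <- c(1, 2, -1) / sqrt(6)
  ax <- matrix(ax0, 50, 3, byrow = TRUE)
  tr <- angle_to_quaternion(th * 180 / pi, ax, t = seq_along(th) / 60)
  aa2 <- to_axis_angle(tr)
  expect_equal(aa2$theta, th, tolerance = 1e-9)
  dots <- rowSums(cbind(aa2$ux, aa2$uy, aa2$uz) * ax)
  expect_equal(dots, rep(1, 50), tolerance = 1e-9)
})

test_that("angular velocity matches analytic rate and the qdot oracle", {
  fs <- 60
  t <- seq(0, 2, by = 1 / fs)
  alpha <- 1.3
  q <- cbind(cos(alpha * t / 2), 0, 0, sin(alpha * t / 2))
  avt <- angular_velocity(orientation_track(t, q))
  inner <- 2:(length(t) - 1)
  expect_equal(avt$wz[inner], rep(alpha, length(inner)), tolerance = 1e-9)
  expect_equal(max(abs(avt$wx)), 0, tolerance = 1e-9)

  static <- orientation_track(t, matrix(quat_normalize(c(1, 2, 3, 4)),
                                        length(t), 4, byrow = TRUE))
  avs <- angular_velocity(static)
  expect_equal(max(abs(as.matrix(avs[, c("wx", "wy", "wz")]))), 0,
               tolerance = 1e-12)

  # 600 Hz smooth rotation: agree with 2 qdot q* within 1e-3 relative
  # (interior samples; both schemes are one-sided at the boundaries)
  tr <- make_wobble_track(fs = 600, dur = 1.5)
  avt2 <- angular_velocity(tr)
  om <- omega_qdot_oracle(tr$t, as_quat_matrix(tr))
  got <- as.matrix(avt2[, c("wx", "wy", "wz")])
  keep <- 2:(nrow(om) - 1)
  rel_err <- max(abs(got[keep, ] - om[keep, ])) / max(abs(om))
  expect_lt(rel_err, 1e-3)
  # halving the step roughly quarters the disagreement (order >= 1)
  tr2 <- make_wobble_track(fs = 1200, dur = 1.5)
  got2 <- as.matrix(angular_velocity(tr2)[, c("wx", "wy", "wz")])
  om2 <- omega_qdot_oracle(tr2$t, as_quat_matrix(tr2))
  keep2 <- 2:(nrow(om2) - 1)
  rel_err2 <- max(abs(got2[keep2, ] - om2[keep2, ])) / max(abs(om2))
  expect_lt(rel_err2, rel_err / 2)

  expect_error(angular_velocity(orientation_track(c(0, 1), matrix(
    c(1, 0, 0, 0), 2, 4, byrow = TRUE))), "3 samples")
})

test_that("axial component projects and normalizes turn direction", {
  avt <- tibble::tibble(t = c(0, 1), wx = c(0, 0), wy = c(0, 0),
                        wz = c(2, 2))
  expect_equal(as.numeric(axial_component(avt, c(0, 0, 1),
                                          normalize_direction = FALSE)),
               c(2, 2))
  avt2 <- tibble::tibble(t = c(0, 1), wx = c(1, 1), wy = c(0.5, 0.5),
                         wz = c(0, 0))
  expect_equal(as.numeric(axial_component(avt2, c(0, 0, 1),
                                          normalize_direction = FALSE)),
               c(0, 0))
  expect_error(axial_component(avt, c(0, 0, 0)), "non-zero")

  # left vs right synthetic turns give identical profiles after normalization
  t <- seq(0, 3, by = 1 / 60)
  v <- lobe_oracle(t, 25, 0.1, -0.4, 0.3) - lobe_oracle(t, 25, 0.8, -0.3, 0.25)
  right <- tibble::tibble(t = t, wx = 0, wy = 0, wz = v * pi / 180)
  left <- tibble::tibble(t = t, wx = 0, wy = 0, wz = -v * pi / 180)
  expect_equal(as.numeric(axial_component(right)),
               as.numeric(axial_component(left)))
})
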