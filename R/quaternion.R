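#' Quaternion algebra for orientation tracks
#'
#' Unit quaternions are stored scalar-first as numeric matrices with columns
#' `qw, qx, qy, qz`, one row per sample. All operations use the Hamilton
#' convention, so composing rotations reads right-to-left:
#' `quat_multiply(a, b)` rotates first by `b`, then by `a`.
#'
#' @param a,b quaternions: numeric vectors of length 4 or n-by-4 matrices
#'   (scalar-first). When both are matrices they must have the same number
#'   of rows; a vector is recycled against a matrix.
#' @return `quat_multiply()` the Hamilton product, `quat_conjugate()` the
#'   conjugate (vector part negated); same shape as the widest input.
#' @examples
#' yaw90 <- c(cos(pi / 4), 0, 0, sin(pi / 4))
#' quat_multiply(yaw90, yaw90)  # 180 degree yaw
#' @export
quat_multiply <- function(a, b) {
  a <- as_quat_matrix(a)
  b <- as_quat_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) {
    stop("quaternion inputs have incompatible numbers of rows", call. = FALSE)
  }
  out <- cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
  colnames(out) <- c("qw", "qx", "qy", "qz")
  if (nrow(out) == 1L) drop(out) else out
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) {
  a <- as_quat_matrix(a)
  out <- cbind(a[, 1], -a[, 2], -a[, 3], -a[, 4])
  colnames(out) <- c("qw", "qx", "qy", "qz")
  if (nrow(out) == 1L) drop(out) else out
}

# coerce vector / matrix / track tibble to an n x 4 matrix, checking finiteness
as_quat_matrix <- function(q) {
  if (is.data.frame(q)) q <- as.matrix(q[, c("qw", "qx", "qy", "qz")])
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  if (ncol(q) != 4L) stop("a quaternion needs 4 components", call. = FALSE)
  if (!all(is.finite(q))) stop("non-finite quaternion component", call. = FALSE)
  q
}

quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  q / sqrt(rowSums(q^2))
}

# enforce hemisphere continuity: consecutive dot products >= 0
quat_hemisphere <- function(q) {
  q <- as_quat_matrix(q)
  if (nrow(q) < 2L) return(q)
  d <- rowSums(q[-1L, , drop = FALSE] * q[-nrow(q), , drop = FALSE])
  flip <- cumprod(ifelse(d < 0, -1, 1))
  q[-1L, ] <- q[-1L, , drop = FALSE] * flip
  q
}

# spherical linear interpolation between unit quaternions q0, q1 at s in [0, 1]
quat_slerp <- function(q0, q1, s) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  if (d > 1 - 1e-10) {
    out <- (1 - s) %o% q0 + s %o% q1
    return(quat_normalize(out))
  }
  th <- acos(min(d, 1))
  (sin((1 - s) * th) %o% q0 + sin(s * th) %o% q1) / sin(th)
}

#' Sensor-to-body alignment from a neutral-pose window
#'
#' During the neutral pose (standing, looking straight ahead) the body frame
#' of every segment is taken as identity, so the alignment quaternion is the
#' conjugate of the sensor's mean orientation over the window. The mean is the
#' normalized arithmetic mean of sign-aligned quaternions, which for tightly
#' clustered orientations agrees with the geodesic mean to second order.
#'
#' @param track an [orientation_track()].
#' @param neutral_window numeric length 2, `c(t_start, t_end)` in seconds.
#' @param min_duration minimum window span covered by samples (s).
#' @param dispersion_warn_deg warn when the angular spread of the window
#'   about its mean exceeds this many degrees (default 5).
#' @return a length-4 alignment quaternion `q_align`; applying it as
#'   `q_align %*% q_sensor(t)` (Hamilton product) yields body orientation.
#' @export
compute_alignment <- function(track, neutral_window, min_duration = 0.5,
                              dispersion_warn_deg = 5) {
  stopifnot(length(neutral_window) == 2L, neutral_window[1] < neutral_window[2])
  sel <- track$t >= neutral_window[1] & track$t <= neutral_window[2]
  if (!any(sel)) stop("neutral window lies outside the track", call. = FALSE)
  tw <- track$t[sel]
  if (max(tw) - min(tw) < min_duration) {
    stop("neutral window covers less than ", min_duration, " s of samples",
         call. = FALSE)
  }
  q <- as_quat_matrix(track[sel, ])
  ref <- q[1L, ]
  sgn <- ifelse(q %*% ref < 0, -1, 1)
  qm <- quat_normalize(colSums(q * as.numeric(sgn)))
  # dispersion: largest geodesic angle from the mean
  dots <- pmin(abs(as_quat_matrix(q) %*% as.numeric(qm)), 1)
  spread <- max(2 * acos(dots)) * 180 / pi
  if (spread > dispersion_warn_deg) {
    warning(sprintf(
      "orientation dispersion in neutral window is %.1f degrees (> %g); %s",
      spread, dispersion_warn_deg, "alignment mean may be unreliable"
    ), call. = FALSE)
  }
  quat_conjugate(as.numeric(qm))
}

#' Apply a fixed alignment rotation to an orientation track
#'
#' @param track an [orientation_track()].
#' @param q_align alignment quaternion from [compute_alignment()].
#' @return the aligned track (`q_align` pre-multiplied sample-wise).
#' @export
apply_alignment <- function(track, q_align) {
  q <- quat_multiply(q_align, as_quat_matrix(track))
  orientation_track(track$t, quat_hemisphere(q),
                    segment = attr(track, "segment"),
                    sampling_rate = attr(track, "sampling_rate"))
}

#' Relative orientation of one segment with respect to another
#'
#' Expresses the head in the trunk frame: `q_rel(t) = q_trunk*(t) (x) q_head(t)`.
#' Both tracks must share a common time base (after alignment).
#'
#' @param head,trunk [orientation_track()]s on the same time base.
#' @return an [orientation_track()] labelled `"relative"`.
#' @export
relative_orientation <- function(head, trunk) {
  if (nrow(head) != nrow(trunk) ||
      max(abs(head$t - trunk$t)) > 1e-9) {
    stop("head and trunk tracks are not on a common time base", call. = FALSE)
  }
  q <- quat_multiply(quat_conjugate(as_quat_matrix(trunk)), as_quat_matrix(head))
  orientation_track(head$t, quat_hemisphere(as_quat_matrix(q)),
                    segment = "relative",
                    sampling_rate = attr(head, "sampling_rate"))
}

#' Axis-angle decomposition of an orientation track
#'
#' Each unit quaternion is written as
#' `q = cos(theta/2) + sin(theta/2) (ux i + uy j + uz k)`, giving the rotation
#' angle `theta = 2 acos(qw)` (scalar part clamped to \[-1, 1\]) and the unit
#' rotation axis from the normalized vector part. Near identity the axis is
#' undefined; it is carried forward from the previous sample (the axial z axis
#' at the first sample) so that axis derivatives stay well behaved.
#'
#' @param track an [orientation_track()] (hemisphere-continuous).
#' @param theta_eps angle (rad) below which the axis is carried forward.
#' @return a tibble with columns `t`, `theta` (rad, in `[0, pi]`), `ux, uy, uz`.
#' @export
to_axis_angle <- function(track, theta_eps = 1e-8) {
  q <- as_quat_matrix(track)
  w <- pmin(pmax(q[, 1], -1), 1)
  theta <- 2 * acos(w)
  vn <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  u <- matrix(NA_real_, nrow(q), 3L)
  last <- c(0, 0, 1)
  for (i in seq_len(nrow(q))) {
    if (theta[i] < theta_eps || vn[i] < theta_eps) {
      u[i, ] <- last
    } else {
      u[i, ] <- q[i, 2:4] / vn[i]
      last <- u[i, ]
    }
  }
  tibble::tibble(t = track$t, theta = theta,
                 ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

# signed-continuous axis-angle form: axis sign flips (which rectify the
# angle near identity and make finite differences of the axis blow up) are
# absorbed into the angle's sign, keeping both series smooth
signed_axis_angle <- function(track) {
  aa <- to_axis_angle(track)
  u <- as.matrix(aa[, c("ux", "uy", "uz")])
  theta <- aa$theta
  ref <- u[1L, ]
  for (i in seq_len(nrow(u))) {
    if (sum(u[i, ] * ref) < 0) {
      u[i, ] <- -u[i, ]
      theta[i] <- -theta[i]
    }
    if (abs(theta[i]) > 1e-6) ref <- u[i, ]
  }
  list(t = aa$t, theta = theta, u = u)
}

#' Angular velocity of an orientation track
#'
#' Computes the body angular velocity from the (sign-continuous) axis-angle
#' form of the track,
#' `omega = theta_dot u + u_dot sin(theta) + (u x u_dot) (1 - cos(theta))`,
#' with `theta_dot` and `u_dot` from central finite differences (one-sided at
#' the ends). For a relative track this is the angular velocity of the head
#' relative to the trunk, expressed in the trunk frame.
#'
#' @param track a uniformly sampled [orientation_track()].
#' @return an `angular_velocity_track` tibble with columns `t`, `wx, wy, wz`
#'   (rad/s).
#' @export
angular_velocity <- function(track) {
  if (nrow(track) < 3L) {
    stop("angular velocity needs at least 3 samples", call. = FALSE)
  }
  aa <- signed_axis_angle(track)
  theta_dot <- finite_diff(aa$theta, aa$t)
  u <- aa$u
  u_dot <- apply(u, 2L, finite_diff, t = aa$t)
  cr <- cbind(
    u[, 2] * u_dot[, 3] - u[, 3] * u_dot[, 2],
    u[, 3] * u_dot[, 1] - u[, 1] * u_dot[, 3],
    u[, 1] * u_dot[, 2] - u[, 2] * u_dot[, 1]
  )
  w <- theta_dot * u + u_dot * sin(aa$theta) + cr * (1 - cos(aa$theta))
  out <- tibble::tibble(t = aa$t, wx = w[, 1], wy = w[, 2], wz = w[, 3])
  class(out) <- c("angular_velocity_track", class(out))
  out
}

# central differences, one-sided at the boundaries
finite_diff <- function(x, t) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

#' Axial component of an angular-velocity track
#'
#' Projects the angular velocity onto the axial (body yaw) axis. With
#' `normalize_direction = TRUE` the sign convention is chosen so that the
#' turn's first velocity lobe is positive, making left and right turns
#' comparable.
#'
#' @param avt an `angular_velocity_track` from [angular_velocity()].
#' @param axis unit 3-vector; defaults to the body yaw axis `c(0, 0, 1)`.
#' @param normalize_direction flip the sign so the first dominant lobe is
#'   positive.
#' @return numeric vector of axial angular velocity (rad/s), with attribute
#'   `"direction"` (+1 or -1) recording any applied flip.
#' @export
axial_component <- function(avt, axis = c(0, 0, 1), normalize_direction = TRUE) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be non-zero", call. = FALSE)
  axis <- axis / nrm
  x <- as.matrix(avt[, c("wx", "wy", "wz")]) %*% axis
  x <- as.numeric(x)
  dir <- 1
  if (normalize_direction && any(x != 0)) dir <- turn_direction(x)
  out <- dir * x
  attr(out, "direction") <- dir
  out
}

# sign that makes the earlier of the two dominant opposite-sign lobes positive
turn_direction <- function(x) {
  imax <- which.max(x)
  imin <- which.min(x)
  if (x[imax] <= 0) return(-1)
  if (x[imin] >= 0) return(1)
  if (imax <= imin) 1 else -1
}
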