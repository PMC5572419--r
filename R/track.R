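#' Orientation track constructor
#'
#' An orientation track is a tibble with a time column `t` (seconds, relative
#' to recording start) and unit-quaternion columns `qw, qx, qy, qz`
#' (scalar-first), carrying the segment label and sampling rate as attributes.
#' Quaternions are normalized and made hemisphere-continuous (consecutive
#' dot products non-negative) on construction.
#'
#' @param t numeric vector of sample times (s), strictly increasing.
#' @param q n-by-4 quaternion matrix or data frame with `qw, qx, qy, qz`.
#' @param segment segment label, one of `"head"`, `"trunk"`, `"pelvis"`,
#'   `"relative"`.
#' @param sampling_rate nominal sampling rate in Hz.
#' @return a tibble of class `orientation_track`.
#' @export
orientation_track <- function(t, q, segment = "trunk", sampling_rate = 60) {
  q <- as_quat_matrix(q)
  stopifnot(length(t) == nrow(q), sampling_rate > 0)
  if (any(diff(t) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  q <- quat_hemisphere(quat_normalize(q))
  out <- tibble::tibble(t = as.numeric(t),
                        qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  attr(out, "segment") <- segment
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("orientation_track", class(out))
  out
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("<orientation_track: %s, %d samples @ %g Hz>\n",
              attr(x, "segment"), nrow(x), attr(x, "sampling_rate")))
  NextMethod()
}

#' Signed axial (yaw) angle of an orientation track
#'
#' Extracts the rotation angle about the body z axis from each quaternion,
#' `yaw = atan2(2(qw qz + qx qy), 1 - 2(qy^2 + qz^2))`, unwrapped so that a
#' continuous rotation does not fold at +/-180 degrees.
#'
#' @param track an [orientation_track()].
#' @return numeric vector of yaw angles in degrees.
#' @export
axial_angle <- function(track) {
  q <- as_quat_matrix(track)
  yaw <- atan2(2 * (q[, 1] * q[, 4] + q[, 2] * q[, 3]),
               1 - 2 * (q[, 3]^2 + q[, 4]^2))
  unwrap_angle(yaw) * 180 / pi
}

unwrap_angle <- function(x) {
  d <- diff(x)
  jump <- ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0))
  x + c(0, cumsum(jump))
}

# pure yaw quaternion from an angle in radians
yaw_quaternion <- function(angle_rad) {
  cbind(qw = cos(angle_rad / 2), qx = 0, qy = 0, qz = sin(angle_rad / 2))
}
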