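#' Assisted detection of cranio-caudal misalignment onset
#'
#' Finds the earliest time at which the largest pairwise axial angle among
#' head, trunk and pelvis exceeds `threshold_deg`, sustained for at least
#' `sustain` seconds. This is an assisted segmentation helper; the final turn
#' boundaries come from heel-strike annotations via [segment_turn()].
#'
#' @param head,trunk,pelvis aligned [orientation_track()]s on a common time
#'   base.
#' @param threshold_deg misalignment threshold (degrees, default 5).
#' @param sustain minimum duration the threshold must stay exceeded (s).
#' @return onset time (s), or `NA` when the threshold is never exceeded.
#' @export
misalignment_onset <- function(head, trunk, pelvis, threshold_deg = 5,
                               sustain = 0.2) {
  pair_angle <- function(a, b) abs(axial_angle(relative_orientation(a, b)))
  m <- pmax(pair_angle(head, trunk), pair_angle(head, pelvis),
            pair_angle(trunk, pelvis))
  over <- m > threshold_deg
  if (!any(over)) return(NA_real_)
  fs <- attr(head, "sampling_rate")
  need <- max(1L, ceiling(sustain * fs))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  head$t[starts[ok[1L]]]
}

#' Turn segment from trial events
#'
#' The turn spans from the heel strike preceding the initial head-trunk
#' misalignment to the heel strike following realignment. When misalignment
#' and realignment times are supplied (e.g. from [misalignment_onset()]) and
#' heel strikes are annotated, the boundaries snap to the bracketing strikes;
#' otherwise the annotated `turn_start`/`turn_end` are used verbatim.
#'
#' @param events a [trial_events()] record.
#' @param misalignment,realignment optional misalignment onset/offset times
#'   (s).
#' @return a `turn_segment` list with `start`, `end`, `source`.
#' @export
segment_turn <- function(events, misalignment = NULL, realignment = NULL) {
  hs <- events$heel_strikes
  if (!is.null(misalignment) && !is.null(realignment) && length(hs)) {
    before <- hs[hs <= misalignment]
    after <- hs[hs >= realignment]
    if (!length(before) || !length(after)) {
      stop("no heel strikes bracket the misalignment window", call. = FALSE)
    }
    seg <- list(start = max(before), end = min(after), source = "assisted")
  } else {
    seg <- list(start = events$turn_start, end = events$turn_end,
                source = "annotation")
  }
  if (seg$start >= seg$end) stop("degenerate turn segment", call. = FALSE)
  structure(seg, class = "turn_segment")
}

#' Maximal head-to-trunk angle during the turn
#'
#' @param angle_deg axial relative angle series (degrees).
#' @param t time grid (s).
#' @param segment a `turn_segment`.
#' @return maximum of `|angle|` within the segment (degrees).
#' @export
h2t_max <- function(angle_deg, t, segment) {
  sel <- t >= segment$start & t <= segment$end
  if (!any(sel)) stop("turn segment lies outside the series", call. = FALSE)
  max(abs(angle_deg[sel]))
}

#' Step count from trunk acceleration
#'
#' Band-passes the vertical trunk acceleration to the gait band
#' (0.5 - 3 Hz) and counts peaks exceeding the segment median by
#' `threshold`, enforcing a 0.25 s refractory separation between steps.
#'
#' @param accel vertical acceleration (m/s^2), full recording.
#' @param t time grid (s).
#' @param segment a `turn_segment`.
#' @param threshold peak height above the segment median (m/s^2).
#' @param sampling_hz sampling rate (Hz).
#' @param band gait frequency band (Hz).
#' @param refractory minimum separation between detected steps (s).
#' @return integer step count.
#' @export
count_steps <- function(accel, t, segment, threshold = 1.2, sampling_hz = 60,
                        band = c(0.5, 3), refractory = 0.25) {
  stopifnot(threshold > 0)
  sel <- t >= segment$start & t <= segment$end
  if (!any(sel)) stop("turn segment lies outside the series", call. = FALSE)
  bf <- signal::butter(2, 2 * band / sampling_hz, type = "pass")
  bp <- filtfilt_ss(bf$b, bf$a, accel - mean(accel))
  x <- bp[sel]
  ts <- t[sel]
  level <- stats::median(x) + threshold
  peaks <- which(diff(sign(diff(x))) == -2) + 1L
  peaks <- peaks[x[peaks] > level]
  if (!length(peaks)) return(0L)
  kept <- peaks[1L]
  for (p in peaks[-1L]) {
    if (ts[p] - ts[kept[length(kept)]] >= refractory) kept <- c(kept, p)
  }
  length(kept)
}

#' Mean and peak turn angular velocity
#'
#' Traditional turn metrics from the trunk gyroscope: mean and maximum of the
#' absolute axial rate over the turn segment.
#'
#' @param gyro_axial axial angular rate (rad/s), full recording.
#' @param t time grid (s).
#' @param segment a `turn_segment`.
#' @return named numeric `c(mean =, max =)` in rad/s.
#' @export
turn_velocity_stats <- function(gyro_axial, t, segment) {
  sel <- t >= segment$start & t <= segment$end
  if (!any(sel)) stop("turn segment lies outside the series", call. = FALSE)
  x <- abs(gyro_axial[sel])
  c(mean = mean(x), max = max(x))
}

#' End-to-end cranio-caudal signature extraction for one trial
#'
#' Runs the full pipeline: sensor-to-body alignment from the neutral window,
#' relative head-to-trunk orientation, zero-phase low-pass filtering of the
#' relative angle (recomposed to quaternion form), the angular-velocity
#' computation, axial projection with turn-direction normalization,
#' segmentation, and the two-phase sigma-lognormal fit. Returns one metrics
#' row; command times `t01`/`t02` and time delays `tbar1`/`tbar2` are
#' reported relative to `cfg$t0_reference` (turn start by default).
#'
#' @param head,trunk [orientation_track()]s for the two segments (sensor
#'   frame; alignment is applied internally).
#' @param events a [trial_events()] record.
#' @param cfg a [run_config()].
#' @param trunk_inertial optional tibble from [read_trunk_inertial()] for
#'   the traditional metrics (`NbSteps`, `turnvel_mean`, `turnvel_max`).
#' @return a one-row tibble with the signature metrics
#'   (`H2Tmax, D1, D2, t01, t02, tbar1, tbar2, s1, s2`), traditional metrics
#'   (NA when no inertial data is given), `SNR`, `qc_pass`, identity columns,
#'   and the fit object in the list-column `fit`.
#' @export
compute_signature <- function(head, trunk, events, cfg = run_config(),
                              trunk_inertial = NULL) {
  q_align_head <- compute_alignment(head, events$neutral_window)
  q_align_trunk <- compute_alignment(trunk, events$neutral_window)
  head_b <- apply_alignment(head, q_align_head)
  trunk_b <- apply_alignment(trunk, q_align_trunk)
  rel <- relative_orientation(head_b, trunk_b)
  rel_f <- filter_orientation_track(rel, cutoff_hz = cfg$cutoff_hz,
                                    order = cfg$filter_order)
  rel_f <- resample_track(rel_f, target_hz = cfg$deriv_hz)
  seg <- segment_turn(events)
  avt <- angular_velocity(rel_f)
  ax <- axial_component(avt, normalize_direction = FALSE)
  sel <- avt$t >= seg$start & avt$t <= seg$end
  dir <- turn_direction(ax[sel])
  v_deg <- dir * ax[sel] * 180 / pi
  t_seg <- avt$t[sel]
  angle <- dir * axial_angle(rel_f)
  fit <- fit_two_phase(v_deg, t_seg, fraction = cfg$p1p5_fraction,
                       refine = cfg$refine, snr_gate_db = cfg$snr_gate_db)
  origin <- if (cfg$t0_reference == "turn_start") seg$start else 0
  comp_or_na <- function(comp, field) {
    if (is.null(comp)) NA_real_ else comp[[field]]
  }
  trad <- c(steps = NA_integer_, mean = NA_real_, max = NA_real_)
  if (!is.null(trunk_inertial)) {
    fs <- attr(trunk, "sampling_rate")
    trad["steps"] <- count_steps(trunk_inertial$az, trunk_inertial$t, seg,
                                 threshold = cfg$step_accel_threshold,
                                 sampling_hz = fs)
    tv <- turn_velocity_stats(trunk_inertial$gz, trunk_inertial$t, seg)
    trad["mean"] <- tv[["mean"]]
    trad["max"] <- tv[["max"]]
  }
  out <- tibble::tibble(
    participant_id = events$participant_id,
    trial_id = events$trial_id,
    pace = events$pace,
    H2Tmax = h2t_max(angle, rel_f$t, seg),
    D1 = comp_or_na(fit$phase1, "D"),
    D2 = comp_or_na(fit$phase2, "D"),
    t01 = comp_or_na(fit$phase1, "t0") - origin,
    t02 = comp_or_na(fit$phase2, "t0") - origin,
    tbar1 = comp_or_na(fit$phase1, "tbar") - origin,
    tbar2 = comp_or_na(fit$phase2, "tbar") - origin,
    s1 = comp_or_na(fit$phase1, "s_resp"),
    s2 = comp_or_na(fit$phase2, "s_resp"),
    NbSteps = trad[["steps"]],
    turnvel_mean = trad[["mean"]],
    turnvel_max = trad[["max"]],
    SNR = fit$snr_db,
    qc_pass = fit$qc_pass,
    fit = list(fit)
  )
  out
}
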