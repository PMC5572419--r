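#' Synthetic-trial configuration
#'
#' Parameters of the synthetic Timed-Up-and-Go turn generator. The defaults
#' describe a healthy older adult turning 180 degrees in about 2.2 s with a
#' two-lognormal head-to-trunk signature of physiological amplitude
#' (command amplitudes near 25 degrees, response times near 0.2 s, the head
#' leading the trunk by about 0.7 s) and modest sensor noise.
#'
#' @param fs sampling rate (Hz).
#' @param turn_angle total trunk yaw of the turn (degrees).
#' @param D1,D2 command amplitudes (degrees). Equal amplitudes realign the
#'   head and trunk at turn end.
#' @param t01,t02 command times relative to turn onset (s).
#' @param mu1,mu2 log time delays.
#' @param sigma1,sigma2 log response times.
#' @param turn_duration trunk yaw ramp duration at normal pace (s).
#' @param pace `"normal"` or `"fast"`; fast scales the trunk ramp duration
#'   by `pace_scale` while the signature ground truth is unchanged.
#' @param pace_scale duration multiplier for fast pace.
#' @param cadence step rate during walking (Hz).
#' @param step_impulse heel-strike acceleration amplitude (m/s^2).
#' @param n_steps steps programmed inside the turn window.
#' @param orientation_noise_deg SD of the small random rotations applied to
#'   each orientation sample (degrees); 0 for noiseless trials.
#' @param accel_noise accelerometer noise SD (m/s^2).
#' @param gyro_noise gyroscope noise SD (rad/s).
#' @param participant_id,trial_id identifiers for the generated records.
#' @param seed integer seed; every random element derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs = 60, turn_angle = 180,
                       D1 = 25, D2 = 25, t01 = 0, t02 = 0.7,
                       mu1 = -0.4, mu2 = -0.3,
                       sigma1 = 0.3, sigma2 = 0.25,
                       turn_duration = 2.2,
                       pace = c("normal", "fast"), pace_scale = 0.75,
                       cadence = 1.8, step_impulse = 3, n_steps = 4,
                       orientation_noise_deg = 0.25,
                       accel_noise = 0.3, gyro_noise = 0.02,
                       participant_id = "P01", trial_id = "T01",
                       seed = 1L) {
  pace <- match.arg(pace)
  stopifnot(fs > 2 * cadence, sigma1 > 0, sigma2 > 0, D1 > 0, D2 > 0,
            turn_duration > 0)
  structure(
    list(fs = fs, turn_angle = turn_angle,
         D1 = D1, D2 = D2, t01 = t01, t02 = t02, mu1 = mu1, mu2 = mu2,
         sigma1 = sigma1, sigma2 = sigma2,
         turn_duration = turn_duration, pace = pace, pace_scale = pace_scale,
         cadence = cadence, step_impulse = step_impulse, n_steps = n_steps,
         orientation_noise_deg = orientation_noise_deg,
         accel_noise = accel_noise, gyro_noise = gyro_noise,
         participant_id = participant_id, trial_id = trial_id,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate one synthetic TUG turn trial
#'
#' Builds head, trunk and pelvis quaternion streams plus trunk inertial
#' channels for a trial with known ground truth: the trunk yaw follows a
#' raised-cosine 180-degree ramp, the head yaw adds the integral of the
#' two-lognormal relative velocity profile, the pelvis follows the trunk
#' with a short lag, gait adds small roll/pitch oscillations and heel-strike
#' acceleration bursts, and fixed sensor-mounting offsets are applied so the
#' neutral-pose alignment step is exercised. All randomness derives from
#' `cfg$seed` (or the `seed` argument); the noiseless relative axial
#' velocity equals the analytic two-lognormal curve by construction.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return a `synthetic_trial` list: `head`, `trunk`, `pelvis`
#'   ([orientation_track()]s), `inertial` tibble, `events`
#'   ([trial_events()]), and `ground_truth` (true parameters, times relative
#'   to turn onset, plus the true relative-angle peak and segment
#'   statistics).
#' @export
make_trial <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed)
  fs <- cfg$fs
  turn_dur <- cfg$turn_duration *
    if (cfg$pace == "fast") cfg$pace_scale else 1
  stand_end <- 1.2
  walk_out <- 2.5
  walk_back <- 2.5
  turn_start <- stand_end + walk_out
  # the signature (or a slow step sequence) may outlast the trunk ramp;
  # annotate the turn to cover both
  sig_end <- cfg$t02 + exp(cfg$mu2 + 4 * cfg$sigma2)
  steps_end <- (cfg$n_steps + 0.5) / cfg$cadence
  turn_end <- turn_start + max(turn_dur, sig_end, steps_end) + 0.3
  t_end <- turn_end + walk_back
  if (turn_start + sig_end >= t_end) {
    stop("phase-2 lobe extends past trial end; lengthen the trial",
         call. = FALSE)
  }
  t <- seq(0, t_end, by = 1 / fs)
  n <- length(t)
  x <- pmin(pmax((t - turn_start) / turn_dur, 0), 1)
  trunk_yaw <- cfg$turn_angle * (1 - cos(pi * x)) / 2   # deg
  v_rel <- lognormal_value(t - turn_start, D = cfg$D1, t0 = cfg$t01,
                           mu = cfg$mu1, sigma = cfg$sigma1) -
    lognormal_value(t - turn_start, D = cfg$D2, t0 = cfg$t02,
                    mu = cfg$mu2, sigma = cfg$sigma2)   # deg/s
  rel_yaw <- cumtrapz(t, v_rel)                          # deg
  pelvis_lag <- 0.15
  pelvis_yaw <- stats::approx(t + pelvis_lag, trunk_yaw, xout = t,
                              rule = 2)$y
  # gait oscillations fade in/out smoothly over 0.5 s around the walk
  move_env <- pmin(1, pmax(0, (t - stand_end) / 0.5)) *
    pmin(1, pmax(0, (turn_end + walk_back - 0.3 - t) / 0.5))
  roll <- 2 * sin(2 * pi * (cfg$cadence / 2) * (t - stand_end)) * move_env
  pitch <- 1 * sin(2 * pi * cfg$cadence * (t - stand_end)) * move_env
  head_bob <- 0.5 * sin(2 * pi * cfg$cadence * (t - stand_end) + 1) *
    move_env
  deg2rad <- pi / 180
  axis_q <- function(angle_deg, axis) {
    half <- angle_deg * deg2rad / 2
    cbind(cos(half), sin(half) * axis[1], sin(half) * axis[2],
          sin(half) * axis[3])
  }
  trunk_body <- quat_multiply(
    quat_multiply(axis_q(trunk_yaw, c(0, 0, 1)), axis_q(roll, c(1, 0, 0))),
    axis_q(pitch, c(0, 1, 0)))
  head_body <- quat_multiply(
    trunk_body,
    quat_multiply(axis_q(rel_yaw, c(0, 0, 1)), axis_q(head_bob, c(0, 1, 0))))
  pelvis_body <- quat_multiply(
    quat_multiply(axis_q(pelvis_yaw, c(0, 0, 1)), axis_q(roll, c(1, 0, 0))),
    axis_q(pitch, c(0, 1, 0)))
  mounts <- list(head = axis_q(12, c(0, 0, 1)),
                 trunk = axis_q(-8, c(0, 0, 1)),
                 pelvis = axis_q(5, c(0, 0, 1)))
  noisy <- function(q_body, mount) {
    q <- quat_multiply(matrix(mount, n, 4, byrow = TRUE), q_body)
    if (cfg$orientation_noise_deg > 0) {
      ang <- stats::rnorm(n, 0, cfg$orientation_noise_deg) * deg2rad
      ax <- matrix(stats::rnorm(3 * n), n, 3)
      ax <- ax / sqrt(rowSums(ax^2))
      qn <- cbind(cos(ang / 2), sin(ang / 2) * ax)
      q <- quat_multiply(q, qn)
    }
    q
  }
  head_q <- noisy(head_body, mounts$head)
  trunk_q <- noisy(trunk_body, mounts$trunk)
  pelvis_q <- noisy(pelvis_body, mounts$pelvis)
  # heel strikes at the walking cadence, n_steps of them inside the turn
  hs_out <- seq(stand_end + 0.3, turn_start, by = 1 / cfg$cadence)
  hs_turn <- turn_start + (seq_len(cfg$n_steps) - 0.25) / cfg$cadence
  hs_back <- seq(turn_end + 0.2, t_end - 0.5, by = 1 / cfg$cadence)
  heel_strikes <- sort(unique(c(hs_out, hs_turn, hs_back)))
  az <- 9.81 + stats::rnorm(n, 0, cfg$accel_noise)
  for (h in heel_strikes) {
    az <- az + cfg$step_impulse * exp(-(t - h)^2 / (2 * 0.08^2))
  }
  trunk_yaw_rate <- finite_diff(trunk_yaw, t) * deg2rad   # rad/s
  inertial <- tibble::tibble(
    t = t,
    ax = stats::rnorm(n, 0, cfg$accel_noise),
    ay = stats::rnorm(n, 0, cfg$accel_noise),
    az = az,
    gx = stats::rnorm(n, 0, cfg$gyro_noise),
    gy = stats::rnorm(n, 0, cfg$gyro_noise),
    gz = trunk_yaw_rate + stats::rnorm(n, 0, cfg$gyro_noise))
  events <- trial_events(
    turn_start = turn_start, turn_end = turn_end,
    neutral_window = c(0.2, 1.0),
    heel_strikes = heel_strikes, pace = cfg$pace,
    participant_id = cfg$participant_id, trial_id = cfg$trial_id)
  seg_sel <- t >= turn_start & t <= turn_end
  ground_truth <- list(
    D1 = cfg$D1, D2 = cfg$D2, t01 = cfg$t01, t02 = cfg$t02,
    mu1 = cfg$mu1, mu2 = cfg$mu2, sigma1 = cfg$sigma1, sigma2 = cfg$sigma2,
    turn_start = turn_start, turn_end = turn_end, turn_duration = turn_dur,
    h2t_max = max(abs(rel_yaw)),
    n_steps_turn = sum(heel_strikes > turn_start & heel_strikes < turn_end),
    turnvel_mean = mean(abs(trunk_yaw_rate[seg_sel])),
    turnvel_max = max(abs(trunk_yaw_rate[seg_sel])),
    seed = cfg$seed)
  structure(
    list(head = orientation_track(t, head_q, "head", fs),
         trunk = orientation_track(t, trunk_q, "trunk", fs),
         pelvis = orientation_track(t, pelvis_q, "pelvis", fs),
         inertial = inertial, events = events,
         ground_truth = ground_truth, config = cfg),
    class = "synthetic_trial"
  )
}

cumtrapz <- function(t, y) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) * diff(t) / 2))
}

#' Generate a synthetic cohort with known variance structure
#'
#' Draws participant-level signature parameters once per participant
#' (between-subject variation) and adds trial-level jitter (within-subject
#' variation), mirroring a 16-participant, two-paces-by-two-repetitions
#' protocol. Command amplitudes scale both phases together so every trial
#' realigns head and trunk; the fast-pace trials shorten the trunk ramp but
#' share the participant's signature ground truth.
#'
#' @param base a [sim_config()] providing the cohort means.
#' @param n_participants number of participants.
#' @param trials_per_condition repetitions of each pace.
#' @param between_sd named list of between-subject SDs:
#'   `D` (degrees, applied to both amplitudes), `mu` (additive on both log
#'   delays), `t02` (s).
#' @param within_sd named list of trial-level SDs on the same elements.
#' @param seed cohort seed; trial seeds derive from it.
#' @return a list of [make_trial()] outputs, one per trial.
#' @export
make_cohort <- function(base = sim_config(), n_participants = 16,
                        trials_per_condition = 2,
                        between_sd = list(D = 8, mu = 0.1, t02 = 0.08),
                        within_sd = list(D = 2, mu = 0.03, t02 = 0.03),
                        seed = 1L) {
  stopifnot(n_participants >= 2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  trials <- list()
  for (i in seq_len(n_participants)) {
    D_i <- max(8, base$D1 + stats::rnorm(1, 0, between_sd$D))
    mu_i <- stats::rnorm(1, 0, between_sd$mu)
    t02_i <- max(0.4, base$t02 + stats::rnorm(1, 0, between_sd$t02))
    for (pace in c("normal", "fast")) {
      for (r in seq_len(trials_per_condition)) {
        cfg <- base
        cfg$participant_id <- sprintf("P%02d", i)
        cfg$trial_id <- sprintf("%s%d", pace, r)
        cfg$pace <- pace
        cfg$D1 <- cfg$D2 <- max(6, D_i + stats::rnorm(1, 0, within_sd$D))
        dmu <- mu_i + stats::rnorm(1, 0, within_sd$mu)
        cfg$mu1 <- base$mu1 + dmu
        cfg$mu2 <- base$mu2 + dmu
        cfg$t02 <- max(0.35, t02_i + stats::rnorm(1, 0, within_sd$t02))
        cfg$seed <- stats::runif(1, 1, 2^30)
        trials[[length(trials) + 1L]] <- make_trial(cfg)
      }
    }
  }
  trials
}

#' Write a synthetic trial to disk
#'
#' Emits the full per-trial file set: three orientation CSVs, the trunk
#' inertial CSV, the events JSON and a ground-truth JSON, into `dir`.
#'
#' @param trial a `synthetic_trial` from [make_trial()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (seg in c("head", "trunk", "pelvis")) {
    readr::write_csv(tibble::as_tibble(trial[[seg]]),
                     file.path(dir, paste0(seg, ".csv")), progress = FALSE)
  }
  readr::write_csv(trial$inertial, file.path(dir, "inertial.csv"),
                   progress = FALSE)
  write_trial_events(trial$events, file.path(dir, "events.json"))
  jsonlite::write_json(trial$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Extract the signature from a synthetic trial
#'
#' Convenience wrapper running [compute_signature()] on the in-memory
#' tracks of a [make_trial()] output.
#'
#' @param trial a `synthetic_trial`.
#' @param cfg a [run_config()].
#' @return the one-row metrics tibble.
#' @export
extract_trial <- function(trial, cfg = run_config()) {
  compute_signature(trial$head, trial$trunk, trial$events, cfg,
                    trunk_inertial = trial$inertial)
}
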