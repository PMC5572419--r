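#' Read an orientation CSV into an orientation track
#'
#' The file format is a plain CSV with header `t,qw,qx,qy,qz`: time in seconds
#' from recording start and a scalar-first unit quaternion per row. Rows must
#' be strictly increasing in time and each quaternion norm must lie within
#' `norm_tol` of 1 (they are re-normalized after the check). Gaps of fewer
#' than `max_gap` missing samples are filled by spherical linear
#' interpolation onto the uniform grid; larger gaps are an error.
#'
#' @param path path to the CSV file.
#' @param segment segment label (`"head"`, `"trunk"` or `"pelvis"`).
#' @param sampling_rate nominal rate in Hz (default 60).
#' @param norm_tol allowed deviation of the quaternion norm from 1.
#' @param max_gap largest run of missing samples that is interpolated.
#' @return an [orientation_track()] on a uniform time base.
#' @export
read_orientation_track <- function(path, segment = "trunk", sampling_rate = 60,
                                   norm_tol = 1e-3, max_gap = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "qw", "qx", "qy", "qz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("orientation file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop("orientation file times are not strictly increasing", call. = FALSE)
  }
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(q^2))
  bad <- which(abs(nrm - 1) > norm_tol)
  if (length(bad)) {
    stop(sprintf("quaternion norm %.4f at data row %d deviates from 1 by more than %g",
                 nrm[bad[1]], bad[1], norm_tol), call. = FALSE)
  }
  res <- fill_gaps_slerp(df$t, quat_hemisphere(quat_normalize(q)),
                         sampling_rate, max_gap)
  orientation_track(res$t, res$q, segment = segment,
                    sampling_rate = sampling_rate)
}

# resample onto the uniform grid implied by sampling_rate, slerping short gaps
fill_gaps_slerp <- function(t, q, fs, max_gap) {
  dt <- 1 / fs
  idx <- round((t - t[1]) / dt)
  if (max(abs(t - (t[1] + idx * dt))) > dt / 4) {
    stop("sample times do not sit on a uniform ", fs, " Hz grid", call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("duplicated sample times", call. = FALSE)
  gaps <- diff(idx) - 1L
  if (any(gaps > max_gap)) {
    stop("gap of ", max(gaps), " missing samples exceeds the ", max_gap,
         "-sample limit", call. = FALSE)
  }
  if (all(gaps == 0L)) return(list(t = t, q = q))
  full <- 0:idx[length(idx)]
  qf <- matrix(NA_real_, length(full), 4L)
  qf[idx + 1L, ] <- q
  for (i in which(gaps > 0L)) {
    k <- gaps[i]
    s <- seq_len(k) / (k + 1)
    qf[(idx[i] + 2L):(idx[i] + 1L + k), ] <- quat_slerp(q[i, ], q[i + 1L, ], s)
  }
  list(t = t[1] + full * dt, q = qf)
}

#' Read a trunk inertial CSV
#'
#' Plain CSV with header `t,ax,ay,az,gx,gy,gz`: time (s), accelerometer
#' (m/s^2) and gyroscope (rad/s) channels in the sensor frame.
#'
#' @param path path to the CSV file.
#' @return a tibble with those columns.
#' @export
read_trunk_inertial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("inertial file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop("inertial file times are not strictly increasing", call. = FALSE)
  }
  df
}

#' Trial event annotations
#'
#' Builds and validates the per-trial event record: the neutral-pose window
#' used for sensor-to-body alignment, annotated heel-strike times, the turn
#' boundaries, and trial identity. All times are seconds from recording start.
#'
#' @param turn_start,turn_end turn boundaries (s), `turn_start < turn_end`.
#' @param neutral_window length-2 window preceding the turn (s).
#' @param heel_strikes sorted heel-strike times (s); may be empty.
#' @param pace `"normal"` or `"fast"`.
#' @param participant_id,trial_id identifier strings.
#' @return a `trial_events` list.
#' @export
trial_events <- function(turn_start, turn_end,
                         neutral_window = c(0, min(0.5, turn_start)),
                         heel_strikes = numeric(0),
                         pace = "normal",
                         participant_id = "P01", trial_id = "T01") {
  if (!is.numeric(turn_start) || !is.numeric(turn_end) ||
      turn_end <= turn_start) {
    stop("turn_end must be greater than turn_start", call. = FALSE)
  }
  if (!pace %in% c("normal", "fast")) {
    stop("pace must be 'normal' or 'fast', got '", pace, "'", call. = FALSE)
  }
  if (length(neutral_window) != 2L || neutral_window[2] <= neutral_window[1]) {
    stop("neutral_window must be an increasing pair of times", call. = FALSE)
  }
  if (neutral_window[2] > turn_start) {
    stop("neutral window must precede turn_start", call. = FALSE)
  }
  heel_strikes <- as.numeric(heel_strikes)
  if (is.unsorted(heel_strikes, strictly = TRUE) && length(heel_strikes) > 1L) {
    stop("heel_strikes must be strictly increasing", call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, trial_id = trial_id, pace = pace,
         neutral_window = as.numeric(neutral_window),
         heel_strikes = heel_strikes,
         turn_start = as.numeric(turn_start), turn_end = as.numeric(turn_end)),
    class = "trial_events"
  )
}

#' Read / write trial events as JSON
#'
#' The events file is a JSON object with keys `participant_id, trial_id,
#' pace, neutral_window, heel_strikes, turn_start, turn_end`. Missing optional
#' keys get the [trial_events()] defaults; invalid values are schema errors.
#'
#' @param path path to the JSON file.
#' @return [read_trial_events()] a validated `trial_events` list;
#'   [write_trial_events()] the path, invisibly.
#' @export
read_trial_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$turn_start) || is.null(x$turn_end)) {
    stop("events file must contain turn_start and turn_end", call. = FALSE)
  }
  args <- list(turn_start = x$turn_start, turn_end = x$turn_end)
  if (!is.null(x$neutral_window)) args$neutral_window <- x$neutral_window
  if (!is.null(x$heel_strikes)) args$heel_strikes <- x$heel_strikes
  if (!is.null(x$pace)) args$pace <- x$pace
  if (!is.null(x$participant_id)) args$participant_id <- x$participant_id
  if (!is.null(x$trial_id)) args$trial_id <- x$trial_id
  do.call(trial_events, args)
}

#' @rdname read_trial_events
#' @param events a `trial_events` object.
#' @export
write_trial_events <- function(events, path) {
  jsonlite::write_json(unclass(events), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Holds the processing parameters of the extraction pipeline with the
#' defaults used throughout: a 4th-order zero-phase Butterworth low-pass at
#' 1.5 Hz on the relative angle, a 2-degree residual threshold for cutoff
#' calibration, a 10 dB signal-to-noise quality gate on the sigma-lognormal
#' reconstruction, and 1%-of-peak initial onset/offset crossings for the
#' characteristic points.
#'
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param filter_order Butterworth order.
#' @param residual_threshold_deg residual threshold for cutoff calibration
#'   (degrees RMS).
#' @param snr_gate_db reconstruction quality gate (dB).
#' @param step_accel_threshold step-detection peak threshold above the
#'   segment median of the band-passed vertical acceleration (m/s^2).
#' @param p1p5_fraction initial onset/offset fraction of peak velocity.
#' @param deriv_hz grid the filtered relative track is spline-resampled to
#'   before numerical differentiation (Hz); see [resample_track()].
#' @param t0_reference time origin for reported command times: `"turn_start"`
#'   or `"recording"`.
#' @param refine polish the point-based two-phase estimate by bounded
#'   nonlinear least squares (default TRUE).
#' @param seed integer seed for any stochastic step (none in extraction;
#'   carried for provenance).
#' @return a `run_config` list.
#' @export
run_config <- function(cutoff_hz = 1.5, filter_order = 4,
                       residual_threshold_deg = 2, snr_gate_db = 10,
                       step_accel_threshold = 1.2, p1p5_fraction = 0.01,
                       deriv_hz = 240,
                       t0_reference = c("turn_start", "recording"),
                       refine = TRUE, seed = 1L) {
  t0_reference <- match.arg(t0_reference)
  stopifnot(cutoff_hz > 0, filter_order >= 1, residual_threshold_deg > 0,
            snr_gate_db > 0, step_accel_threshold > 0,
            p1p5_fraction > 0, p1p5_fraction < 0.5, deriv_hz > 0)
  structure(
    list(cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
         residual_threshold_deg = residual_threshold_deg,
         snr_gate_db = snr_gate_db,
         step_accel_threshold = step_accel_threshold,
         p1p5_fraction = p1p5_fraction, deriv_hz = deriv_hz,
         t0_reference = t0_reference,
         refine = isTRUE(refine), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path path to a JSON file whose keys override the defaults.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

metric_columns <- c("participant_id", "trial_id", "pace",
                    "H2Tmax", "D1", "D2", "t01", "t02", "tbar1", "tbar2",
                    "s1", "s2", "NbSteps", "turnvel_mean", "turnvel_max",
                    "SNR", "qc_pass")

#' Write / read the per-trial metrics table
#'
#' Tab-separated, one row per trial, with the signature metric columns
#' (`H2Tmax, D1, D2, t01, t02, tbar1, tbar2, s1, s2`), the traditional
#' metrics (`NbSteps, turnvel_mean, turnvel_max`), the reconstruction `SNR`
#' (dB) and the quality flag `qc_pass`. Rows failing quality control are
#' written too; filtering happens downstream in the reliability stage.
#'
#' @param rows tibble of per-trial metrics (from [compute_signature()]).
#' @param path output path.
#' @return [write_metrics_table()] the path invisibly;
#'   [read_metrics_table()] the tibble.
#' @export
write_metrics_table <- function(rows, path) {
  if (nrow(rows) == 0L) {
    rows <- tibble::as_tibble(stats::setNames(
      rep(list(logical(0)), length(metric_columns)), metric_columns))
  }
  missing_cols <- setdiff(metric_columns, names(rows))
  if (length(missing_cols)) {
    stop("metrics rows are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_tsv(rows[, metric_columns], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    participant_id = "c", trial_id = "c", pace = "c",
                    qc_pass = "l", NbSteps = "d", .default = "d"))
}
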