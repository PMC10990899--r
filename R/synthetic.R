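# Synthetic labelled weightlifting sessions: two wrist IMU streams with
# activity-distinct signatures, heart-rate drift toward a plateau, and
# Borg-RPE reports generated from a linear RPE-vs-relative-heart-rate line.

#' Default per-activity signal signatures
#'
#' Each of the four lift phases gets a per-channel-group sinusoid + offset
#' signature: grip is near-static (low acceleration variance, stable
#' angles), lift-off and clean-and-jerk are dynamic with different dominant
#' frequencies, and set-down mirrors lift-off with an inverted angle trend.
#' Amplitudes are in g (acceleration), deg/s (gyro) and deg (angles);
#' frequencies in Hz; `angle_trend` in deg/s within a segment.
#'
#' @param amp_scale multiply all oscillation amplitudes (0 gives constant
#'   signatures, useful for degenerate-case tests).
#' @return named list of signature parameter lists, one per activity.
#' @export
default_signatures <- function(amp_scale = 1) {
  sig <- function(acc_off, acc_amp, acc_freq, gyr_amp, gyr_freq,
                  ang_off, ang_amp, ang_freq, ang_trend) {
    list(acc_off = acc_off, acc_amp = acc_amp * amp_scale, acc_freq = acc_freq,
         gyr_amp = gyr_amp * amp_scale, gyr_freq = gyr_freq,
         ang_off = ang_off, ang_amp = ang_amp * amp_scale,
         ang_freq = ang_freq, ang_trend = ang_trend * amp_scale)
  }
  list(
    grip           = sig(c(0.00, 0.00, 1.00), 0.05, 0.5,   5, 0.5,
                         c(10,  0,  5), 2, 0.5,  0),
    lift_off       = sig(c(0.20, 0.05, 1.05), 0.50, 1.2,  60, 1.2,
                         c(45, 10, 10), 15, 1.2,  8),
    clean_and_jerk = sig(c(0.35, 0.10, 1.10), 1.20, 2.2, 150, 2.2,
                         c(90, 20, 15), 25, 2.2,  0),
    set_down       = sig(c(-0.20, 0.05, 1.05), 0.45, 1.1,  55, 1.1,
                         c(45, 10, 10), 15, 1.1, -8)
  )
}

#' Specify a synthetic training session
#'
#' The default schedule emulates a five-set lift protocol: each set runs
#' grip, lift-off, clean-and-jerk, set-down back to back. Heart rate rises
#' exponentially from the resting value toward `hr_plateau` times rest
#' (time constant `hr_tau_min` minutes) with AR(1) minute-to-minute noise,
#' and an RPE report is generated at every 5-minute mark from the linear
#' relative-heart-rate line, rounded to the integer Borg scale.
#'
#' @param seed integer RNG seed; sessions are deterministic given it.
#' @param n_sets number of grip/lift-off/clean-and-jerk/set-down sets.
#' @param set_pattern named durations (s) of the four phases within a set.
#' @param signature_params per-activity signatures, see [default_signatures()].
#' @param noise_sd Gaussian noise sd added to every IMU channel, in that
#'   channel group's units (a single number, scaled x1 for acceleration,
#'   x20 for gyro, x4 for angles to keep signal-to-noise comparable).
#' @param sample_rate_hz IMU sampling rate (nominal 50).
#' @param resting_hr_bpm resting heart rate Hc.
#' @param hr_plateau asymptotic relative heart rate (default 1.55, inside
#'   the observed 30-minute range 1.46-1.64).
#' @param hr_tau_min exponential time constant of the heart-rate rise.
#' @param hr_noise_sd sd of the AR(1) disturbance on relative heart rate.
#' @param rpe_slope,rpe_intercept,rpe_noise_sd the latent RPE line
#'   `rpe = slope * Hr + intercept + noise`; defaults are the fitted
#'   fatigue-model coefficients.
#' @return an object of class `SessionSpec`.
#' @export
session_spec <- function(seed = 1L,
                         n_sets = 5L,
                         set_pattern = c(grip = 8, lift_off = 5,
                                         clean_and_jerk = 7, set_down = 5),
                         signature_params = default_signatures(),
                         noise_sd = 0.05,
                         sample_rate_hz = 50,
                         resting_hr_bpm = 72,
                         hr_plateau = 1.55,
                         hr_tau_min = 8,
                         hr_noise_sd = 0.01,
                         rpe_slope = 16.12343,
                         rpe_intercept = -10.36787,
                         rpe_noise_sd = 0.5) {
  if (!all(names(set_pattern) %in% ACTIVITY_NAMES))
    stop("set_pattern names must be among: ", paste(ACTIVITY_NAMES, collapse = ", "))
  if (any(set_pattern <= 0)) stop("set_pattern durations must be positive")
  if (noise_sd < 0 || hr_noise_sd < 0 || rpe_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (resting_hr_bpm <= 0) stop("resting_hr_bpm must be positive")
  if (hr_plateau < 1) stop("hr_plateau must be >= 1")
  missing_sig <- setdiff(ACTIVITY_NAMES, names(signature_params))
  if (length(missing_sig))
    stop("signature_params missing activities: ", paste(missing_sig, collapse = ", "))
  schedule <- data.frame(
    activity = rep(names(set_pattern), times = n_sets),
    duration_s = rep(unname(set_pattern), times = n_sets)
  )
  structure(
    list(seed = as.integer(seed), schedule = schedule,
         signature_params = signature_params, noise_sd = noise_sd,
         sample_rate_hz = sample_rate_hz, resting_hr_bpm = resting_hr_bpm,
         hr_plateau = hr_plateau, hr_tau_min = hr_tau_min,
         hr_noise_sd = hr_noise_sd,
         rpe_line = list(slope = rpe_slope, intercept = rpe_intercept,
                         noise_sd = rpe_noise_sd)),
    class = "SessionSpec"
  )
}

# Latent RPE line evaluated at a relative heart rate, administered as the
# integer Borg 6-20 scale: rounding and clipping happen only here.
rpe_from_hr <- function(hr_rel, line, noise = 0) {
  raw <- line$slope * hr_rel + line$intercept + noise
  pmin(pmax(round(raw), 6L), 20L)
}

one_wrist <- function(spec, phase_shift) {
  fs <- spec$sample_rate_hz
  seg_n <- round(spec$schedule$duration_s * fs)
  n <- sum(seg_n)
  t <- (seq_len(n) - 1L) / fs
  out <- matrix(0, n, 9L, dimnames = list(NULL, SENSOR_CHANNELS))
  # per-channel phase offsets keep the nine channels linearly independent
  ph <- phase_shift + (0:8) * (pi / 7)
  row0 <- 0L
  for (i in seq_len(nrow(spec$schedule))) {
    sg <- spec$signature_params[[spec$schedule$activity[i]]]
    idx <- row0 + seq_len(seg_n[i])
    tt <- t[idx]
    tl <- tt - tt[1]
    for (a in 1:3) {
      out[idx, a]     <- sg$acc_off[a] +
        sg$acc_amp * sin(2 * pi * sg$acc_freq * tt + ph[a])
      out[idx, 3 + a] <- sg$gyr_amp * sin(2 * pi * sg$gyr_freq * tt + ph[3 + a])
      out[idx, 6 + a] <- sg$ang_off[a] + sg$ang_trend * tl +
        sg$ang_amp * sin(2 * pi * sg$ang_freq * tt + ph[6 + a])
    }
    row0 <- row0 + seg_n[i]
  }
  if (spec$noise_sd > 0) {
    noise_scale <- rep(c(1, 20, 4), each = 3L)
    out <- out + matrix(stats::rnorm(n * 9L, sd = spec$noise_sd), n, 9L) %*%
      diag(noise_scale)
  }
  out
}

#' Simulate one labelled training session
#'
#' Generates both wrist streams (right wrist phase-shifted relative to the
#' left), the heart-rate series with its resting baseline, RPE reports at
#' 5-minute marks, and the ground-truth label track. Deterministic given
#' `spec$seed`.
#'
#' @param spec a `SessionSpec` from [session_spec()].
#' @return list with elements `left`, `right` (`SensorStream`), `hr`
#'   (`HeartRateSeries`), `rpe` (data.frame minute/rpe), `labels`
#'   (`LabelTrack`).
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "SessionSpec"))
  set.seed(spec$seed)
  left <- sensor_stream(one_wrist(spec, 0), spec$sample_rate_hz, "left_wrist")
  right <- sensor_stream(one_wrist(spec, pi / 5), spec$sample_rate_hz, "right_wrist")

  ends <- cumsum(spec$schedule$duration_s)
  labels <- label_track(data.frame(
    start_s = c(0, ends[-length(ends)]),
    end_s = ends,
    code = ACTIVITY_CODES[spec$schedule$activity]
  ))

  duration_min <- max(1L, floor(sum(spec$schedule$duration_s) / 60))
  minutes <- seq_len(duration_min)
  hr_rel <- 1 + (spec$hr_plateau - 1) * (1 - exp(-minutes / spec$hr_tau_min))
  if (spec$hr_noise_sd > 0) {
    eps <- stats::rnorm(duration_min, sd = spec$hr_noise_sd)
    ar <- Reduce(function(prev, e) 0.6 * prev + e, eps, accumulate = TRUE)
    hr_rel <- hr_rel + ar
  }
  hr_rel <- pmax(hr_rel, 1)
  hr <- heart_rate_series(spec$resting_hr_bpm,
                          data.frame(minute = minutes,
                                     hr_bpm = spec$resting_hr_bpm * hr_rel))

  marks <- minutes[minutes %% 5 == 0]
  rpe_noise <- if (spec$rpe_line$noise_sd > 0)
    stats::rnorm(length(marks), sd = spec$rpe_line$noise_sd) else rep(0, length(marks))
  rpe <- data.frame(minute = marks,
                    rpe = rpe_from_hr(hr_rel[marks], spec$rpe_line, rpe_noise))

  list(left = left, right = right, hr = hr, rpe = rpe, labels = labels)
}

#' Simulate a cohort of subjects
#'
#' Jitters resting heart rate, heart-rate plateau, signature amplitudes and
#' the RPE line around a base specification; subject seeds derive
#' deterministically from the base seed plus the subject index.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_spec a `SessionSpec`.
#' @param variation list of normal-jitter standard deviations:
#'   `resting_hr_sd` (bpm), `plateau_sd`, `amp_scale_sd` (multiplicative,
#'   around 1), `rpe_slope_sd`, `rpe_intercept_sd`. Zero spread reproduces
#'   the base spec for every subject.
#' @return list of session bundles as returned by [simulate_session()];
#'   each carries its `spec` as an attribute.
#' @export
make_cohort <- function(n_subjects, base_spec = session_spec(),
                        variation = list(resting_hr_sd = 4, plateau_sd = 0.05,
                                         amp_scale_sd = 0.1,
                                         rpe_slope_sd = 0.8,
                                         rpe_intercept_sd = 0.8)) {
  stopifnot(n_subjects >= 1, inherits(base_spec, "SessionSpec"))
  v <- utils::modifyList(list(resting_hr_sd = 0, plateau_sd = 0,
                              amp_scale_sd = 0, rpe_slope_sd = 0,
                              rpe_intercept_sd = 0), variation)
  set.seed(base_spec$seed)
  jit <- matrix(stats::rnorm(n_subjects * 5L), n_subjects, 5L)
  lapply(seq_len(n_subjects), function(i) {
    spec <- base_spec
    spec$seed <- base_spec$seed + i
    spec$resting_hr_bpm <- max(40, base_spec$resting_hr_bpm +
                                 jit[i, 1] * v$resting_hr_sd)
    spec$hr_plateau <- max(1, base_spec$hr_plateau + jit[i, 2] * v$plateau_sd)
    amp <- max(0.2, 1 + jit[i, 3] * v$amp_scale_sd)
    spec$signature_params <- lapply(base_spec$signature_params, function(sg) {
      sg$acc_amp <- sg$acc_amp * amp
      sg$gyr_amp <- sg$gyr_amp * amp
      sg$ang_amp <- sg$ang_amp * amp
      sg
    })
    spec$rpe_line$slope <- base_spec$rpe_line$slope + jit[i, 4] * v$rpe_slope_sd
    spec$rpe_line$intercept <- base_spec$rpe_line$intercept +
      jit[i, 5] * v$rpe_intercept_sd
    out <- simulate_session(spec)
    attr(out, "spec") <- spec
    out
  })
}

#' Write a simulated session to a directory
#'
#' Emits the four canonical file types (`left.imu.csv`, `right.imu.csv`,
#' `session.hr.csv`, `session.rpe.csv`, `session.labels.csv`) so that the
#' file-based pipeline entry points can consume a synthetic session.
#'
#' @param session a bundle from [simulate_session()].
#' @param dir output directory, created if missing.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sensor_log(session$left, file.path(dir, "left.imu.csv"))
  write_sensor_log(session$right, file.path(dir, "right.imu.csv"))
  write_heart_rate_log(session$hr, file.path(dir, "session.hr.csv"))
  write_rpe_log(session$rpe, file.path(dir, "session.rpe.csv"))
  write_label_track(session$labels, file.path(dir, "session.labels.csv"))
  invisible(dir)
}
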