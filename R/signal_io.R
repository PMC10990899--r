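# Canonical channel order as logged by one wrist unit: tri-axial
# acceleration (g), angular velocity (deg/s), fused attitude angles (deg).
SENSOR_CHANNELS <- c(
  "acc_x", "acc_y", "acc_z",
  "gyr_x", "gyr_y", "gyr_z",
  "ang_x", "ang_y", "ang_z"
)

ACTIVITY_CODES <- c(grip = 1L, lift_off = 2L, clean_and_jerk = 3L, set_down = 4L)
ACTIVITY_NAMES <- names(ACTIVITY_CODES)

activity_name <- function(code) ACTIVITY_NAMES[as.integer(code)]

#' Construct a sensor stream
#'
#' A `SensorStream` holds the multichannel inertial time series from one
#' wrist placement: a regular grid of samples at `sample_rate_hz`, nine
#' channels (3 acceleration, 3 angular velocity, 3 attitude angle).
#'
#' @param samples numeric matrix, one row per tick, nine named columns.
#' @param sample_rate_hz positive sampling rate (nominally 50 Hz).
#' @param placement `"left_wrist"` or `"right_wrist"`.
#' @param t0 elapsed-seconds origin of the first sample (default 0).
#' @return an object of class `SensorStream`.
#' @export
sensor_stream <- function(samples, sample_rate_hz = 50,
                          placement = c("left_wrist", "right_wrist"),
                          t0 = 0) {
  placement <- match.arg(placement)
  samples <- as.matrix(samples)
  if (ncol(samples) != 9L)
    stop("a sensor stream has exactly 9 channels, got ", ncol(samples))
  if (is.null(colnames(samples))) colnames(samples) <- SENSOR_CHANNELS
  if (!identical(colnames(samples), SENSOR_CHANNELS))
    stop("channel names must be, in order: ",
         paste(SENSOR_CHANNELS, collapse = ", "))
  if (anyNA(samples)) stop("sensor stream contains missing values")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  structure(
    list(placement = placement, sample_rate_hz = sample_rate_hz,
         t0 = t0, channels = SENSOR_CHANNELS, samples = samples),
    class = "SensorStream"
  )
}

#' @export
print.SensorStream <- function(x, ...) {
  cat(sprintf("<SensorStream> %s: %d samples x %d channels @ %g Hz (%.1f s)\n",
              x$placement, nrow(x$samples), ncol(x$samples),
              x$sample_rate_hz, stream_duration(x)))
  invisible(x)
}

#' Duration of a stream in seconds
#' @param stream a `SensorStream`.
#' @export
stream_duration <- function(stream) nrow(stream$samples) / stream$sample_rate_hz

#' Write an inertial log
#'
#' The canonical dialect is CSV with a `# sample_rate_hz: <rate>` comment
#' line, then a header `time_s,<nine channel names>`, one row per tick.
#' Values are written with full double precision so that a write/read
#' round trip is bit-identical.
#'
#' @param stream a `SensorStream`.
#' @param path output file path (conventionally `*.imu.csv`).
#' @export
write_sensor_log <- function(stream, path) {
  stopifnot(inherits(stream, "SensorStream"))
  n <- nrow(stream$samples)
  t <- stream$t0 + (seq_len(n) - 1L) / stream$sample_rate_hz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %.17g", stream$sample_rate_hz), con)
  writeLines(paste(c("time_s", stream$channels), collapse = ","), con)
  body <- apply(cbind(t, stream$samples), 1L,
                function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

read_declared_rate <- function(first_line, path) {
  m <- regmatches(first_line,
                  regexec("^#\\s*sample_rate_hz:\\s*([0-9.eE+-]+)", first_line))[[1]]
  if (length(m) < 2L)
    stop("format error in ", path,
         ": missing '# sample_rate_hz:' declaration on line 1")
  rate <- as.numeric(m[2])
  if (!is.finite(rate) || rate <= 0)
    stop("format error in ", path, ": declared rate must be positive")
  rate
}

#' Read an inertial log
#'
#' Validates the canonical dialect written by [write_sensor_log()]: every
#' row must parse to ten numeric cells (time + nine channels); a malformed
#' or incomplete row is a parse error naming its line number. Ticks must be
#' equally spaced; duplicate timestamps are rejected, and a declared rate
#' disagreeing with the median inter-sample gap by more than 10% is a
#' format error. Gaps are never silently filled.
#'
#' @param path path to a `*.imu.csv` file.
#' @param placement which wrist the log came from.
#' @return a validated `SensorStream`.
#' @export
read_sensor_log <- function(path, placement = c("left_wrist", "right_wrist")) {
  placement <- match.arg(placement)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error in ", path, ": file too short")
  rate <- read_declared_rate(lines[1], path)
  header <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (!identical(header, c("time_s", SENSOR_CHANNELS)))
    stop("format error in ", path, ": header must name time_s and the nine channels")
  body <- lines[-(1:2)]
  cells <- strsplit(body, ",", fixed = TRUE)
  bad_len <- which(lengths(cells) != 10L)
  if (length(bad_len))
    stop("parse error in ", path, " at line ", bad_len[1] + 2L,
         ": expected 10 fields, found ", lengths(cells)[bad_len[1]])
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(10L)))
  bad_num <- which(apply(vals, 2L, anyNA))
  if (length(bad_num))
    stop("parse error in ", path, " at line ", bad_num[1] + 2L,
         ": non-numeric or missing cell")
  vals <- t(vals)
  t <- vals[, 1]
  if (anyDuplicated(t)) {
    dup <- which(duplicated(t))[1]
    stop("format error in ", path, " at line ", dup + 2L,
         ": duplicate timestamp ", t[dup])
  }
  if (length(t) > 1L) {
    gaps <- diff(t)
    med <- stats::median(gaps)
    if (any(abs(gaps - med) > med * 0.01))
      stop("format error in ", path, ": samples are not equally spaced")
    if (abs(1 / med - rate) > 0.1 * rate)
      stop("format error in ", path, ": declared rate ", rate,
           " Hz disagrees with median inter-sample gap (", signif(1 / med, 6), " Hz)")
  }
  m <- vals[, -1, drop = FALSE]
  colnames(m) <- SENSOR_CHANNELS
  sensor_stream(m, sample_rate_hz = rate, placement = placement, t0 = t[1])
}

#' Construct a heart-rate series
#'
#' Holds the resting heart rate Hc (mean over a seated pre-exercise
#' window) and the per-minute exercise means Hw.
#'
#' @param resting_hr_bpm positive resting heart rate Hc.
#' @param minutes data.frame with columns `minute` (strictly increasing
#'   integer index, first exercise minute = 1) and `hr_bpm`.
#' @export
heart_rate_series <- function(resting_hr_bpm, minutes) {
  stopifnot(is.numeric(resting_hr_bpm), resting_hr_bpm > 0)
  minutes <- as.data.frame(minutes)
  if (!all(c("minute", "hr_bpm") %in% names(minutes)))
    stop("minutes needs columns 'minute' and 'hr_bpm'")
  if (nrow(minutes) == 0L) stop("heart-rate series has no exercise minutes")
  if (any(minutes$hr_bpm <= 0)) stop("all per-minute heart rates must be positive")
  if (is.unsorted(minutes$minute, strictly = TRUE))
    stop("minute indices must be strictly increasing")
  structure(list(resting_hr_bpm = resting_hr_bpm,
                 minutes = minutes[c("minute", "hr_bpm")]),
            class = "HeartRateSeries")
}

#' @export
print.HeartRateSeries <- function(x, ...) {
  cat(sprintf("<HeartRateSeries> Hc = %.1f bpm, %d exercise minutes\n",
              x$resting_hr_bpm, nrow(x$minutes)))
  invisible(x)
}

#' Write a heart-rate log
#'
#' Dialect: CSV `time_s,bpm,segment` with `segment` in `rest`/`exercise`.
#' The resting window is written as one reading per minute at Hc; exercise
#' minutes as one reading each.
#'
#' @param hr a `HeartRateSeries`.
#' @param path output path (conventionally `*.hr.csv`).
#' @param resting_window_min minutes of rest readings to emit.
#' @export
write_heart_rate_log <- function(hr, path, resting_window_min = 5) {
  stopifnot(inherits(hr, "HeartRateSeries"))
  rest_t <- (seq_len(resting_window_min) - 1L) * 60
  ex_t <- max(rest_t) + 60 + (hr$minutes$minute - 1L) * 60
  df <- data.frame(
    time_s = c(rest_t, ex_t),
    bpm = c(rep(hr$resting_hr_bpm, length(rest_t)), hr$minutes$hr_bpm),
    segment = c(rep("rest", length(rest_t)), rep("exercise", nrow(hr$minutes)))
  )
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heart-rate log
#'
#' Hc is the mean of the rest-segment readings; Hw is the mean of each
#' exercise minute's readings (minutes counted from the start of the
#' exercise segment). The rest segment must span at least
#' `resting_window_min` minutes.
#'
#' @param path path to a `*.hr.csv` file.
#' @param resting_window_min required length of the resting window.
#' @return a `HeartRateSeries`.
#' @export
read_heart_rate_log <- function(path, resting_window_min = 5) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "bpm", "segment")
  if (!all(need %in% names(df)))
    stop("format error in ", path, ": need columns ", paste(need, collapse = ", "))
  rest <- df[df$segment == "rest", , drop = FALSE]
  ex <- df[df$segment == "exercise", , drop = FALSE]
  if (nrow(rest) == 0L) stop("no resting segment in ", path)
  if (nrow(ex) == 0L) stop("no exercise segment in ", path)
  span <- diff(range(rest$time_s))
  gap <- if (nrow(rest) > 1L) stats::median(diff(sort(rest$time_s))) else 0
  if (span + gap < resting_window_min * 60 - 1e-9)
    stop("resting segment shorter than ", resting_window_min, " minutes in ", path)
  minute <- floor((ex$time_s - min(ex$time_s)) / 60) + 1L
  hw <- tapply(ex$bpm, minute, mean)
  heart_rate_series(mean(rest$bpm),
                    data.frame(minute = as.integer(names(hw)),
                               hr_bpm = as.numeric(hw)))
}

#' Write RPE reports
#'
#' @param rpe data.frame with columns `minute` and `rpe` (Borg 6-20).
#' @param path output path (conventionally `*.rpe.csv`).
#' @export
write_rpe_log <- function(rpe, path) {
  rpe <- validate_rpe(rpe)
  utils::write.csv(rpe, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_rpe <- function(rpe) {
  rpe <- as.data.frame(rpe)
  if (!all(c("minute", "rpe") %in% names(rpe)))
    stop("RPE table needs columns 'minute' and 'rpe'")
  if (nrow(rpe) && (any(rpe$rpe < 6) || any(rpe$rpe > 20)))
    stop("RPE values must lie in the Borg 6-20 range")
  rpe[c("minute", "rpe")]
}

#' Read RPE reports
#' @param path path to a `*.rpe.csv` file.
#' @return data.frame with columns `minute`, `rpe`, validated to Borg 6-20.
#' @export
read_rpe_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_rpe(utils::read.csv(path))
}

#' Construct a label track
#'
#' Ground-truth activity intervals: half-open `[start_s, end_s)` spans
#' carrying activity codes 1 = grip, 2 = lift-off, 3 = clean-and-jerk,
#' 4 = set-down. Intervals must be sorted and non-overlapping.
#'
#' @param intervals data.frame with columns `start_s`, `end_s`, `code`.
#' @export
label_track <- function(intervals) {
  intervals <- as.data.frame(intervals)
  need <- c("start_s", "end_s", "code")
  if (!all(need %in% names(intervals)))
    stop("label track needs columns ", paste(need, collapse = ", "))
  intervals <- intervals[need]
  if (nrow(intervals)) {
    if (!all(intervals$code %in% 1:4))
      stop("activity codes must be in 1..4")
    if (any(intervals$end_s <= intervals$start_s))
      stop("intervals must have positive duration")
    if (is.unsorted(intervals$start_s))
      stop("intervals must be sorted by start time")
    if (any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)]))
      stop("intervals must not overlap")
  }
  intervals$code <- as.integer(intervals$code)
  structure(list(intervals = intervals), class = "LabelTrack")
}

#' Write a label track
#' @param labels a `LabelTrack`.
#' @param path output path (conventionally `*.labels.csv`).
#' @export
write_label_track <- function(labels, path) {
  stopifnot(inherits(labels, "LabelTrack"))
  df <- labels$intervals
  df$start_s <- sprintf("%.17g", df$start_s)
  df$end_s <- sprintf("%.17g", df$end_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label track
#' @param path path to a `*.labels.csv` file.
#' @export
read_label_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  label_track(utils::read.csv(path))
}
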