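# Windowing and time-domain feature extraction. The pipeline keeps an
# explicit (identity) denoising stage: data are collected with the units
# strapped down, so no additional filtering is applied, but the stage
# exists so the processing graph is complete and extensible.

#' Denoise a sensor stream
#'
#' The only supported strategy is `"none"`: with a fixed-mount collection
#' strategy the raw signal is used as-is. The stage is an explicit identity
#' so alternative strategies can slot in without changing the pipeline.
#'
#' @param stream a `SensorStream`.
#' @param strategy denoising strategy; only `"none"` is supported.
#' @return the stream, unchanged.
#' @export
denoise <- function(stream, strategy = "none") {
  stopifnot(inherits(stream, "SensorStream"))
  if (!identical(strategy, "none"))
    stop("unsupported denoising strategy: ", strategy,
         " (only 'none' is available)")
  stream
}

#' Default 12-channel feature subset
#'
#' Both wrists' acceleration and attitude-angle channels (2 placements x 6
#' channels = 12): the activity signatures show up mainly as acceleration
#' and angle variation. An accel+gyro subset is equally valid; pass it
#' explicitly to [extract_features()].
#'
#' @export
default_feature_channels <- function() {
  c(paste0("left_", SENSOR_CHANNELS[c(1:3, 7:9)]),
    paste0("right_", SENSOR_CHANNELS[c(1:3, 7:9)]))
}

#' Segment two wrist streams into fixed sliding windows
#'
#' Tiles the common time span of both streams with fixed-length windows of
#' `window_len_s` seconds advancing by `window_len_s * (1 -
#' overlap_fraction)` (default 5 s windows, 50% overlap). Windows are
#' half-open `[start, start + len)`; trailing samples shorter than one
#' window are dropped. When a `LabelTrack` is supplied each window gets the
#' activity code occupying the majority of it, ties going to the
#' earlier-starting interval.
#'
#' @param left,right the two `SensorStream`s (same sampling rate).
#' @param labels optional `LabelTrack`.
#' @param window_len_s window length in seconds.
#' @param overlap_fraction fraction of overlap between consecutive windows,
#'   in `[0, 1)`.
#' @return an object of class `WindowSet`: window array (samples x
#'   channels x windows), start times, parameters, optional labels.
#' @export
segment <- function(left, right, labels = NULL,
                    window_len_s = 5, overlap_fraction = 0.5) {
  stopifnot(inherits(left, "SensorStream"), inherits(right, "SensorStream"))
  if (window_len_s <= 0) stop("window_len_s must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (left$sample_rate_hz != right$sample_rate_hz)
    stop("both streams must share one sampling rate")
  fs <- left$sample_rate_hz
  n <- min(nrow(left$samples), nrow(right$samples))
  spw <- round(window_len_s * fs)
  step <- round(window_len_s * (1 - overlap_fraction) * fs)
  if (step < 1L) stop("window step is below one sample")
  channels <- c(paste0("left_", SENSOR_CHANNELS), paste0("right_", SENSOR_CHANNELS))
  starts_idx <- seq.int(1L, by = step, length.out = max(0L, (n - spw) %/% step + 1L))
  if (n < spw) starts_idx <- integer(0)
  if (!length(starts_idx)) {
    warning("common span shorter than one window; empty WindowSet")
    return(structure(list(windows = array(0, c(spw, length(channels), 0L)),
                          starts_s = numeric(0), window_len_s = window_len_s,
                          overlap_fraction = overlap_fraction,
                          sample_rate_hz = fs, labels = NULL),
                     class = "WindowSet"))
  }
  joint <- cbind(left$samples[seq_len(n), , drop = FALSE],
                 right$samples[seq_len(n), , drop = FALSE])
  colnames(joint) <- channels
  w <- array(0, c(spw, length(channels), length(starts_idx)),
             dimnames = list(NULL, channels, NULL))
  for (k in seq_along(starts_idx))
    w[, , k] <- joint[starts_idx[k] + 0:(spw - 1L), ]
  starts_s <- (starts_idx - 1L) / fs
  lab <- NULL
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "LabelTrack"))
    lab <- vapply(starts_s, function(s0)
      window_majority_label(labels, s0, s0 + window_len_s), integer(1))
  }
  structure(list(windows = w, starts_s = starts_s,
                 window_len_s = window_len_s,
                 overlap_fraction = overlap_fraction,
                 sample_rate_hz = fs, labels = lab),
            class = "WindowSet")
}

# Majority occupancy over [w0, w1); ties go to the earlier-starting
# interval (intervals are sorted, so the first maximum wins).
window_majority_label <- function(labels, w0, w1) {
  iv <- labels$intervals
  ov <- pmax(0, pmin(iv$end_s, w1) - pmax(iv$start_s, w0))
  if (all(ov == 0)) return(NA_integer_)
  per_code <- vapply(split(ov, iv$code), sum, numeric(1))
  # earliest interval start per code breaks exact ties deterministically
  first_start <- vapply(split(iv$start_s[ov > 0], iv$code[ov > 0]),
                        min, numeric(1))
  cand <- names(per_code)[per_code == max(per_code)]
  if (length(cand) > 1L)
    cand <- cand[which.min(first_start[cand])]
  as.integer(cand)
}

#' @export
print.WindowSet <- function(x, ...) {
  cat(sprintf("<WindowSet> %d windows of %g s (%.0f%% overlap), %d channels\n",
              dim(x$windows)[3], x$window_len_s, 100 * x$overlap_fraction,
              dim(x$windows)[2]))
  invisible(x)
}

FEATURE_STATS <- c("mean", "sd", "iqr", "kurtosis", "skewness", "autocov")

# Lag-1 autocovariance about the window mean, denominator n - 1. This is
# the per-channel reading of the "covariance" feature: with six statistics
# per channel and twelve channels the vector must stay 72-dimensional, so
# the covariance must be a within-channel quantity. The alternative
# cov_with_time reading (covariance of the sample with elapsed time, i.e.
# a trend measure) is selectable.
lag1_autocov <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  m <- mean(x)
  sum((x[-n] - m) * (x[-1] - m)) / (n - 1)
}

channel_features <- function(x, covariance) {
  s <- stats::sd(x)
  if (s == 0) {
    sk <- 0
    ku <- 0
  } else {
    sk <- e1071::skewness(x, type = 2)
    ku <- e1071::kurtosis(x, type = 2)
  }
  cv <- if (covariance == "lag1_autocov") lag1_autocov(x)
        else stats::cov(x, seq_along(x))
  c(mean(x), s,
    unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE))),
    ku, sk, cv)
}

#' Extract the 72-dimensional time-domain feature vector per window
#'
#' For each of 12 channels computes six statistics — mean, sample standard
#' deviation (n-1), interquartile range (type-7 linear-interpolation
#' quantiles), excess kurtosis, adjusted Fisher-Pearson skewness, and a
#' covariance feature (lag-1 autocovariance by default) — giving the
#' feature vector C = (c1, ..., c72). Column order is, for each channel in
#' the given order, the six statistics in the order listed. Zero-variance
#' windows get skewness and kurtosis 0 so features are always finite.
#'
#' @param ws a `WindowSet`.
#' @param channels ordered character vector of 12 channel identifiers.
#' @param covariance `"lag1_autocov"` (default) or `"cov_with_time"`.
#' @return data.frame with 72 feature columns (named
#'   `<channel>.<statistic>`) plus a `label` column when the window set is
#'   labelled; class `FeatureTable`.
#' @export
extract_features <- function(ws, channels = default_feature_channels(),
                             covariance = c("lag1_autocov", "cov_with_time")) {
  stopifnot(inherits(ws, "WindowSet"))
  covariance <- match.arg(covariance)
  if (length(channels) != 12L)
    stop("exactly 12 channels are required, got ", length(channels))
  missing_ch <- setdiff(channels, dimnames(ws$windows)[[2]])
  if (length(missing_ch))
    stop("channels not present in the window set: ",
         paste(missing_ch, collapse = ", "))
  if (dim(ws$windows)[1] < 4L)
    stop("windows must contain at least 4 samples for kurtosis")
  nw <- dim(ws$windows)[3]
  feat_names <- as.vector(t(outer(channels, FEATURE_STATS, paste, sep = ".")))
  m <- matrix(NA_real_, nw, length(feat_names), dimnames = list(NULL, feat_names))
  for (k in seq_len(nw)) {
    block <- ws$windows[, channels, k, drop = FALSE]
    m[k, ] <- as.vector(vapply(seq_along(channels), function(j)
      channel_features(block[, j, 1L], covariance), numeric(6)))
  }
  if (anyNA(m) || any(!is.finite(m)))
    stop("non-finite feature values computed")
  out <- as.data.frame(m)
  if (!is.null(ws$labels)) out$label <- ws$labels
  attr(out, "feature_names") <- feat_names
  class(out) <- c("FeatureTable", "data.frame")
  out
}

feature_names <- function(features) {
  setdiff(names(features), "label")
}
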