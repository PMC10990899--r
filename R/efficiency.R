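# Training-efficiency scoring: per-activity time accounting over
# overlapping windows, the effective training rate theta = Te / T, and the
# three-level efficiency rating.

#' Accumulate per-activity time from window predictions
#'
#' With overlapping windows a naive per-window sum counts most of the
#' session twice; instead each window contributes the step duration
#' `window_len_s * (1 - overlap_fraction)`, except the final window which
#' contributes the full window length, so the per-activity times sum
#' exactly to the span covered by the windows.
#'
#' @param predictions integer activity codes aligned to the windows.
#' @param window_len_s window length in seconds.
#' @param overlap_fraction window overlap fraction.
#' @return named numeric: seconds per activity (grip, lift_off,
#'   clean_and_jerk, set_down).
#' @export
accumulate_time <- function(predictions, window_len_s = 5,
                            overlap_fraction = 0.5) {
  out <- stats::setNames(numeric(4), ACTIVITY_NAMES)
  if (!length(predictions)) {
    warning("no predictions; all activity times are zero")
    return(out)
  }
  if (!all(predictions %in% 1:4)) stop("activity codes must be in 1..4")
  step <- window_len_s * (1 - overlap_fraction)
  contrib <- c(rep(step, length(predictions) - 1L), window_len_s)
  for (k in seq_along(predictions))
    out[predictions[k]] <- out[predictions[k]] + contrib[k]
  out
}

#' Effective training rate
#'
#' theta = Te / T: lift-off and clean-and-jerk count as effective training
#' time Te; grip (auxiliary) and set-down (non-training) complete the
#' total T.
#'
#' @param per_activity_time_s named seconds per activity, as from
#'   [accumulate_time()].
#' @return theta in `[0, 1]`.
#' @export
effective_training_rate <- function(per_activity_time_s) {
  total <- sum(per_activity_time_s)
  if (total <= 0) stop("total training time must be positive")
  unname((per_activity_time_s[["lift_off"]] +
            per_activity_time_s[["clean_and_jerk"]]) / total)
}

#' Three-level efficiency rating
#'
#' low: theta < 0.35; medium: 0.35 <= theta <= 0.55 (both boundaries in
#' the closed middle band); high: theta > 0.55.
#'
#' @param theta effective training rate in `[0, 1]`.
#' @return `"low"`, `"medium"` or `"high"` (ordered factor levels
#'   low < medium < high).
#' @export
rate_efficiency <- function(theta) {
  if (!is.finite(theta) || theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]")
  if (theta < 0.35) "low" else if (theta <= 0.55) "medium" else "high"
}

#' Full efficiency result for a window prediction track
#'
#' @param predictions integer activity codes aligned to the windows.
#' @param window_len_s,overlap_fraction window geometry.
#' @return `EfficiencyResult`: per-activity times, category times
#'   (effective / auxiliary / non_training), theta and the rating.
#' @export
efficiency_result <- function(predictions, window_len_s = 5,
                              overlap_fraction = 0.5) {
  times <- accumulate_time(predictions, window_len_s, overlap_fraction)
  theta <- effective_training_rate(times)
  structure(list(
    per_activity_time_s = times,
    category_time_s = c(
      effective = unname(times[["lift_off"]] + times[["clean_and_jerk"]]),
      auxiliary = unname(times[["grip"]]),
      non_training = unname(times[["set_down"]])
    ),
    theta = theta,
    rating = rate_efficiency(theta)
  ), class = "EfficiencyResult")
}

#' @export
print.EfficiencyResult <- function(x, ...) {
  cat(sprintf("<EfficiencyResult> theta = %.3f (%s efficiency)\n",
              x$theta, x$rating))
  t <- x$per_activity_time_s
  cat(sprintf("  grip %.1fs | lift-off %.1fs | clean-and-jerk %.1fs | set-down %.1fs\n",
              t[["grip"]], t[["lift_off"]], t[["clean_and_jerk"]],
              t[["set_down"]]))
  invisible(x)
}

#' Bar chart of per-activity time shares
#'
#' @param efficiency an `EfficiencyResult`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_time_share <- function(efficiency, ...) {
  t <- efficiency$per_activity_time_s
  graphics::barplot(100 * t / sum(t),
                    names.arg = c("grip", "lift-off", "clean&jerk", "set-down"),
                    ylab = "share of session time (%)", ...)
  invisible(efficiency)
}
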