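# Physiological-fatigue model: relative heart rate Hr = Hw / Hc, an
# ordinary-least-squares line from Hr to the Borg RPE score, and the
# three-level training-load rating.

#' Relative heart rate
#'
#' Hr = Hw / Hc: instantaneous (per-minute mean) heart rate over the
#' resting heart rate. Normalises out individual resting-rate differences.
#'
#' @param hw_bpm instantaneous heart rate(s), bpm.
#' @param hc_bpm resting heart rate, bpm.
#' @export
relative_heart_rate <- function(hw_bpm, hc_bpm) {
  if (any(hw_bpm <= 0) || any(hc_bpm <= 0))
    stop("heart rates must be positive")
  hw_bpm / hc_bpm
}

#' Construct a fatigue model from known coefficients
#'
#' The model is the affine map `rpe = slope * Hr + intercept`. Use this to
#' instantiate a previously fitted model (fit diagnostics unknown: NA).
#'
#' @param slope,intercept model coefficients.
#' @return a `FatigueModel`.
#' @export
fatigue_model <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept,
                 r2_adj = NA_real_, f_stat = NA_real_, n = NA_integer_),
            class = "FatigueModel")
}

#' Fit the RPE-vs-relative-heart-rate fatigue model
#'
#' Ordinary least squares of the Borg RPE score on relative heart rate,
#' with the adjusted coefficient of determination and the regression
#' F statistic as fit diagnostics.
#'
#' @param hr_rel relative heart rates (>= 3 values, not all identical).
#' @param rpe RPE scores paired with `hr_rel`.
#' @return a `FatigueModel` with `slope`, `intercept`, `r2_adj`, `f_stat`,
#'   `n`.
#' @export
fit_fatigue_model <- function(hr_rel, rpe) {
  stopifnot(length(hr_rel) == length(rpe))
  if (length(hr_rel) < 3L) stop("need at least 3 (Hr, RPE) pairs")
  if (stats::sd(hr_rel) == 0)
    stop("relative heart rates are all identical; cannot fit a slope")
  fit <- stats::lm(rpe ~ hr_rel)
  sm <- summary(fit)
  fstat <- if (is.null(sm$fstatistic)) 0 else unname(sm$fstatistic[1])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2_adj = sm$adj.r.squared,
                 f_stat = fstat,
                 n = length(hr_rel)),
            class = "FatigueModel")
}

#' @export
print.FatigueModel <- function(x, ...) {
  cat(sprintf("<FatigueModel> rpe = %.5f * Hr %+.5f", x$slope, x$intercept))
  if (!is.na(x$r2_adj))
    cat(sprintf("  (adj R2 %.3f, F %.2f, n %d)", x$r2_adj, x$f_stat, x$n))
  cat("\n")
  invisible(x)
}

#' Predict fatigue intensity (RPE scale) from relative heart rate
#'
#' `y = slope * Hr + intercept`, deliberately NOT clipped to the Borg 6-20
#' range: a prediction above 20 signals significantly intense training and
#' is flagged downstream rather than hidden.
#'
#' @param model a `FatigueModel`.
#' @param hr_rel relative heart rate(s), > 0.
#' @return predicted RPE value(s).
#' @export
predict_rpe <- function(model, hr_rel) {
  stopifnot(inherits(model, "FatigueModel"))
  if (any(hr_rel <= 0)) stop("relative heart rate must be positive")
  model$slope * hr_rel + model$intercept
}

#' Three-level training-load rating
#'
#' low: Hr < 1.33; medium: 1.33 <= Hr <= 1.57 (closed band); high:
#' Hr > 1.57. Every positive Hr maps to exactly one level.
#'
#' @param hr_rel relative heart rate, > 0.
#' @param model optional `FatigueModel` used to attach the predicted RPE.
#' @return a `LoadRating` list: `hr_rel`, `level`, `predicted_rpe`
#'   (NA without a model), `intense` (TRUE when predicted RPE exceeds 20).
#' @export
rate_load <- function(hr_rel, model = NULL) {
  if (!is.finite(hr_rel) || hr_rel <= 0)
    stop("relative heart rate must be positive")
  level <- if (hr_rel < 1.33) "low" else if (hr_rel <= 1.57) "medium" else "high"
  pred <- if (is.null(model)) NA_real_ else predict_rpe(model, hr_rel)
  structure(list(hr_rel = hr_rel, level = level, predicted_rpe = pred,
                 intense = !is.na(pred) && pred > 20),
            class = "LoadRating")
}

#' @export
print.LoadRating <- function(x, ...) {
  cat(sprintf("<LoadRating> Hr = %.3f -> %s load", x$hr_rel, x$level))
  if (!is.na(x$predicted_rpe))
    cat(sprintf(" (predicted RPE %.1f%s)", x$predicted_rpe,
                if (x$intense) ", significantly intense" else ""))
  cat("\n")
  invisible(x)
}

#' Per-minute and session-level load summary
#'
#' Computes per-minute relative heart rate, predicted RPE and load level,
#' plus a session-level rating taken at the aggregate relative heart rate
#' (mean by default; max and final-minute aggregation available).
#'
#' @param hr a `HeartRateSeries`.
#' @param model a `FatigueModel`.
#' @param aggregate session aggregation of Hr: `"mean"`, `"max"` or
#'   `"final"`.
#' @return list with `per_minute` data.frame (minute, hw_bpm, hr_rel,
#'   predicted_rpe, level, intense) and `session` (a `LoadRating`).
#' @export
session_load_summary <- function(hr, model, aggregate = c("mean", "max", "final")) {
  stopifnot(inherits(hr, "HeartRateSeries"), inherits(model, "FatigueModel"))
  aggregate <- match.arg(aggregate)
  hr_rel <- relative_heart_rate(hr$minutes$hr_bpm, hr$resting_hr_bpm)
  pred <- predict_rpe(model, hr_rel)
  per_minute <- data.frame(
    minute = hr$minutes$minute,
    hw_bpm = hr$minutes$hr_bpm,
    hr_rel = hr_rel,
    predicted_rpe = pred,
    level = vapply(hr_rel, function(h) rate_load(h)$level, character(1)),
    intense = pred > 20
  )
  agg_hr <- switch(aggregate,
                   mean = mean(hr_rel),
                   max = max(hr_rel),
                   final = hr_rel[length(hr_rel)])
  list(per_minute = per_minute, session = rate_load(agg_hr, model))
}
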