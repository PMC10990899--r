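# Nine-state efficiency-load assessment: the 3x3 cross of {low, medium,
# high} training load x {low, medium, high} training efficiency, each
# state carrying a fixed management recommendation, plus the end-to-end
# session pipeline.

REPORT_VERSION <- "1.0"

#' Load the nine-state recommendation catalogue
#'
#' Reads the editable CSV catalogue shipped with the package (or a
#' user-supplied replacement) keyed by (load level, efficiency level).
#'
#' @param path optional path to an alternative catalogue CSV with columns
#'   `load`, `efficiency`, `recommendation`.
#' @return data.frame with one row per state (9 rows).
#' @export
load_recommendations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "recommendations.csv", package = "trainload")
  cat9 <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("load", "efficiency", "recommendation")
  if (!all(need %in% names(cat9)))
    stop("recommendation catalogue needs columns ", paste(need, collapse = ", "))
  levels3 <- c("low", "medium", "high")
  keys <- paste(cat9$load, cat9$efficiency)
  want <- as.vector(outer(levels3, levels3, paste))
  if (!setequal(keys, want) || anyDuplicated(keys))
    stop("catalogue must contain exactly the 9 (load, efficiency) states")
  cat9
}

#' Fuse efficiency and load into the nine-state session assessment
#'
#' Pure lookup in the 3x3 state catalogue; total over the nine states.
#'
#' @param efficiency an `EfficiencyResult`.
#' @param load a session-level `LoadRating`.
#' @param catalogue optional catalogue from [load_recommendations()].
#' @return a `SessionAssessment`: `state` (load level, efficiency level),
#'   `recommendation`, plus the two inputs.
#' @export
assess <- function(efficiency, load, catalogue = load_recommendations()) {
  stopifnot(inherits(efficiency, "EfficiencyResult"),
            inherits(load, "LoadRating"))
  row <- catalogue[catalogue$load == load$level &
                     catalogue$efficiency == efficiency$rating, ]
  structure(list(
    state = c(load = load$level, efficiency = efficiency$rating),
    recommendation = row$recommendation[1],
    efficiency = efficiency,
    load = load
  ), class = "SessionAssessment")
}

#' @export
print.SessionAssessment <- function(x, ...) {
  cat(sprintf("<SessionAssessment> load %s / efficiency %s\n",
              x$state[["load"]], x$state[["efficiency"]]))
  cat("  theta =", sprintf("%.3f", x$efficiency$theta),
      "| session Hr =", sprintf("%.3f", x$load$hr_rel), "\n")
  cat("  recommendation:", x$recommendation, "\n")
  invisible(x)
}

assessment_report <- function(assessment, load_summary) {
  list(
    report_version = REPORT_VERSION,
    state = as.list(assessment$state),
    recommendation = assessment$recommendation,
    efficiency = list(
      theta = assessment$efficiency$theta,
      rating = assessment$efficiency$rating,
      per_activity_time_s = as.list(assessment$efficiency$per_activity_time_s),
      category_time_s = as.list(assessment$efficiency$category_time_s)
    ),
    load = list(
      session_hr_rel = assessment$load$hr_rel,
      level = assessment$load$level,
      predicted_rpe = assessment$load$predicted_rpe,
      intense = assessment$load$intense
    ),
    per_minute = load_summary$per_minute
  )
}

report_text <- function(report) {
  pm <- report$per_minute
  c(sprintf("Session assessment (report v%s)", report$report_version),
    sprintf("  load: %s | efficiency: %s", report$state$load,
            report$state$efficiency),
    sprintf("  effective training rate theta = %.3f (%s)",
            report$efficiency$theta, report$efficiency$rating),
    sprintf("  session relative heart rate = %.3f (%s), predicted RPE %.1f%s",
            report$load$session_hr_rel, report$load$level,
            report$load$predicted_rpe,
            if (isTRUE(report$load$intense)) " [significantly intense]" else ""),
    sprintf("  recommendation: %s", report$recommendation),
    "",
    "  per-activity time (s):",
    sprintf("    %-15s %8.1f", names(report$efficiency$per_activity_time_s),
            unlist(report$efficiency$per_activity_time_s)),
    "",
    "  per-minute load:",
    "    minute   Hw(bpm)    Hr  pred.RPE  level",
    sprintf("    %6d  %8.1f  %5.3f  %7.1f  %s", pm$minute, pm$hw_bpm,
            pm$hr_rel, pm$predicted_rpe, pm$level))
}

#' Run the full session-assessment pipeline on a session directory
#'
#' Reads the four canonical file types from `session_dir`
#' (`left.imu.csv`, `right.imu.csv`, `session.hr.csv`, optionally
#' `session.rpe.csv` and `session.labels.csv`), then executes
#' denoise -> segment -> extract_features -> predict -> efficiency on the
#' inertial side and heart-rate ingest -> session load summary on the
#' physiological side, fusing both with [assess()]. Optionally writes
#' `report.json` and `report.txt`.
#'
#' @param session_dir directory holding the session files.
#' @param model a trained `activity_model`.
#' @param fatigue_model a `FatigueModel`.
#' @param out_dir optional output directory for the report files.
#' @param window_len_s,overlap_fraction window geometry.
#' @param channels feature channel subset.
#' @param aggregate session load aggregation (see [session_load_summary()]).
#' @return invisibly, a list with `assessment` (`SessionAssessment`) and
#'   `report` (the full report structure).
#' @export
run_pipeline <- function(session_dir, model, fatigue_model, out_dir = NULL,
                         window_len_s = 5, overlap_fraction = 0.5,
                         channels = default_feature_channels(),
                         aggregate = "mean") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  left <- stage("read", read_sensor_log(file.path(session_dir, "left.imu.csv"),
                                        "left_wrist"))
  right <- stage("read", read_sensor_log(file.path(session_dir, "right.imu.csv"),
                                         "right_wrist"))
  hr <- stage("read", read_heart_rate_log(file.path(session_dir, "session.hr.csv")))
  left <- stage("denoise", denoise(left))
  right <- stage("denoise", denoise(right))
  ws <- stage("segment", segment(left, right, labels = NULL,
                                 window_len_s = window_len_s,
                                 overlap_fraction = overlap_fraction))
  feats <- stage("features", extract_features(ws, channels = channels))
  pred <- stage("predict", predict_activity(model, feats))
  eff <- stage("efficiency", efficiency_result(pred, window_len_s,
                                               overlap_fraction))
  load_sum <- stage("load", session_load_summary(hr, fatigue_model,
                                                 aggregate = aggregate))
  assessment <- stage("assess", assess(eff, load_sum$session))
  report <- assessment_report(assessment, load_sum)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(out_dir, c("report.json", "report.txt"))))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(report_text(report), file.path(out_dir, "report.txt"))
    ok <- TRUE
  }
  invisible(list(assessment = assessment, report = report))
}
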