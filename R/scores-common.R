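# shared helpers for the scoring layer

require_fields <- function(cohort, fields, model) {
  absent <- setdiff(fields, names(cohort))
  if (length(absent) > 0)
    stop(model, ": missing required column(s): ",
         paste(absent, collapse = ", "))
  has_na <- fields[vapply(fields, function(f) anyNA(cohort[[f]]), TRUE)]
  if (length(has_na) > 0)
    stop(model, ": missing value(s) in required field(s): ",
         paste(has_na, collapse = ", "),
         " (impute or complete the cohort before scoring)")
  invisible(TRUE)
}

score_components <- function(model, total, age_points, predicted_risk = NULL) {
  out <- data.frame(model = model, total = total, age_points = age_points,
                    non_age_points = total - age_points,
                    stringsAsFactors = FALSE)
  out$predicted_risk <- if (is.null(predicted_risk)) NA_real_ else predicted_risk
  class(out) <- c("score_components", "data.frame")
  out
}

#' Physical activity status for the CAIDE inactivity item
#'
#' A participant counts as physically active with at least `min_minutes`
#' (default 40) minutes per week of activity at MET intensity 4 or higher.
#' When weekly minutes at MET >= 4 are unavailable, total leisure MET-hours
#' are used through an equivalent-energy threshold (40 min at MET 4 =
#' 8/3 MET-hours), an approximation documented in the methods vignette.
#'
#' @param cohort A cohort data frame.
#' @param min_minutes Minutes/week of MET >= 4 activity required.
#' @return Logical vector (`TRUE` = active), `NA` where neither activity
#'   field is observed.
#' @export
is_physically_active <- function(cohort, min_minutes = 40) {
  met_hours_threshold <- min_minutes / 60 * 4
  act <- cohort$active_minutes_met4 >= min_minutes
  fallback <- cohort$physical_activity_met_hours >= met_hours_threshold
  ifelse(is.na(act), fallback, act)
}
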