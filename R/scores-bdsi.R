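#' Brief Dementia Screening Indicator (BDSI)
#'
#' Point score developed for ages 65-79 to flag candidates for cognitive
#' screening: age contributes 1 point per year; education under 12 years 9
#' points; BMI under 18.5 kg/m2 8 points; diabetes 3; history of stroke 6;
#' needing assistance with finances or medications 10; depressive symptoms
#' 6. The non-age component ranges 0-42.
#'
#' The published score anchors age only as "1 point/year"; here
#' `age_points = age - age_anchor` with anchor 65 (zero points at the lower
#' design age). Any affine shift of the anchor leaves rank-based validation
#' metrics unchanged. Outside the 65-79 design range the score is only
#' computed when `extrapolate_age = TRUE`, extending the same 1 point/year
#' slope (the adaptation used to compare models across a wider cohort).
#'
#' @param cohort A cohort data frame with complete `age`, `education_years`,
#'   `bmi`, `diabetes`, `stroke`, `needs_help_finances_medications`,
#'   `depressive_symptoms`.
#' @param extrapolate_age Allow ages outside 65-79.
#' @param age_anchor Age at which the age component is zero.
#' @return A `score_components` data frame.
#' @examples
#' p <- data.frame(age = 70, education_years = 14, bmi = 25, diabetes = TRUE,
#'                 stroke = TRUE, needs_help_finances_medications = FALSE,
#'                 depressive_symptoms = FALSE)
#' bdsi_score(p)$total  # 5 age points + 3 + 6 = 14
#' @export
bdsi_score <- function(cohort, extrapolate_age = FALSE, age_anchor = 65) {
  require_fields(cohort, c("age", "education_years", "bmi", "diabetes",
                           "stroke", "needs_help_finances_medications",
                           "depressive_symptoms"), "BDSI")
  if (!extrapolate_age && any(cohort$age < 65 | cohort$age > 79))
    stop("BDSI: age outside the 65-79 design range; ",
         "set extrapolate_age = TRUE to extend the 1 point/year slope")
  age_pts <- cohort$age - age_anchor
  non_age <- (cohort$education_years < 12) * 9 +
    (cohort$bmi < 18.5) * 8 +
    cohort$diabetes * 3 +
    cohort$stroke * 6 +
    cohort$needs_help_finances_medications * 10 +
    cohort$depressive_symptoms * 6
  score_components("BDSI", as.numeric(age_pts + non_age), as.numeric(age_pts))
}
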