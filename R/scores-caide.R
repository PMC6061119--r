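#' CAIDE dementia risk score
#'
#' Midlife cardiovascular risk score: age (under 47 years: 0; 47-53: 3;
#' over 53: 4 points), male sex (1), education (>= 10 years: 0; 7-9: 2;
#' 0-6: 3), systolic blood pressure > 140 mmHg (2), BMI > 30 kg/m2 (2),
#' total cholesterol > 6.5 mmol/L (2) and physical inactivity (1). Category
#' boundaries follow the published strict inequalities; education is floored
#' to whole years before banding. Total ranges 0-15.
#'
#' In a cohort aged entirely over 53 the age component is constant, so the
#' age-only variant carries no discriminative information; [score_variant()]
#' flags this degeneracy.
#'
#' @param cohort A cohort data frame with complete `age`, `sex`,
#'   `education_years`, `sbp`, `bmi`, `total_cholesterol` and at least one
#'   activity field per row.
#' @param min_active_minutes Passed to [is_physically_active()].
#' @return A `score_components` data frame with columns `model`, `total`,
#'   `age_points`, `non_age_points`, `predicted_risk` (`NA`: the published
#'   score has no bundled absolute-risk mapping).
#' @examples
#' p <- data.frame(age = 60, sex = "male", education_years = 5, sbp = 150,
#'                 bmi = 31, total_cholesterol = 7,
#'                 physical_activity_met_hours = 1, active_minutes_met4 = 10)
#' caide_score(p)$total  # 15
#' @export
caide_score <- function(cohort, min_active_minutes = 40) {
  active <- is_physically_active(cohort, min_active_minutes)
  cohort$.active <- active
  require_fields(cohort, c("age", "sex", "education_years", "sbp", "bmi",
                           "total_cholesterol", ".active"), "CAIDE")
  age_pts <- ifelse(cohort$age < 47, 0, ifelse(cohort$age <= 53, 3, 4))
  edu <- floor(cohort$education_years)
  edu_pts <- ifelse(edu >= 10, 0, ifelse(edu >= 7, 2, 3))
  total <- age_pts +
    (cohort$sex == "male") * 1 +
    edu_pts +
    (cohort$sbp > 140) * 2 +
    (cohort$bmi > 30) * 2 +
    (cohort$total_cholesterol > 6.5) * 2 +
    (!active) * 1
  score_components("CAIDE", as.numeric(total), as.numeric(age_pts))
}
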