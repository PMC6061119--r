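#' Default ANU-ADRI age-by-sex point grid
#'
#' The published index assigns age points stratified by sex, from 0 points
#' for men under 65 up to 41 points for women aged 90 or over. Only those
#' two endpoints are fixed by the published description used here; the
#' intermediate bands live in supplementary material that is not bundled.
#' This default grid is therefore a synthetic reconstruction: five-year
#' bands, monotone in age, women weighted at or above men, matching the
#' published endpoints. Override it (or load one from CSV with
#' [read_anu_age_grid()]) when the exact published grid is available.
#'
#' @return Data frame with columns `age_lo` (inclusive lower band edge),
#'   `male`, `female`.
#' @export
anu_default_age_grid <- function() {
  data.frame(
    age_lo = c(-Inf, 65, 70, 75, 80, 85, 90),
    male   = c(0, 2, 5, 10, 15, 21, 26),
    female = c(0, 5, 11, 18, 26, 34, 41))
}

#' Read an ANU-ADRI age-by-sex grid from CSV
#'
#' Expects columns `age_lo`, `male`, `female`; `age_lo` is the inclusive
#' lower edge of each band and the first band should start at `-Inf` (any
#' non-numeric first value is taken as `-Inf`).
#'
#' @param path CSV path.
#' @return Grid data frame as in [anu_default_age_grid()].
#' @export
read_anu_age_grid <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_lo", "male", "female") %in% names(g)))
    stop("age grid needs columns age_lo, male, female")
  g$age_lo <- suppressWarnings(as.numeric(g$age_lo))
  g$age_lo[1] <- -Inf
  if (is.unsorted(g$age_lo) || is.unsorted(g$male) || is.unsorted(g$female))
    stop("age grid must be monotone in age and points")
  g
}

anu_age_points <- function(age, sex, grid) {
  band <- findInterval(age, grid$age_lo)
  ifelse(sex == "male", grid$male[band], grid$female[band])
}

#' Map the 3-domain social composite to ANU-ADRI social-network categories
#'
#' Adverse-state count over living status, marital status and loneliness
#' (not living with a partner, not married, lonely), mapped 0/1/2/3 to
#' high / medium-high / medium-low / low social network.
#'
#' @param living_with_partner,married,lonely Logical vectors.
#' @return Factor with levels `high`, `medium_high`, `medium_low`, `low`.
#' @export
social_network_composite <- function(living_with_partner, married, lonely) {
  k <- (!living_with_partner) + (!married) + lonely
  factor(c("high", "medium_high", "medium_low", "low")[k + 1],
         levels = c("high", "medium_high", "medium_low", "low"))
}

#' ANU Alzheimer's Disease Risk Index (ANU-ADRI)
#'
#' Self-report risk index over 15 factors. Points as published: age-by-sex
#' grid (see [anu_default_age_grid()]); education 8-11 years: 3, over 11
#' years: 6 (as printed -- this runs opposite to the usual protective
#' direction of education; override via `education_points` if desired);
#' diabetes 3; traumatic brain injury 4; depressive symptoms 2; high
#' cholesterol 3; social network high/medium-high/medium-low/low
#' 0/1/4/6; smoking former 1, current 4; light-to-moderate alcohol -3;
#' physical activity medium -2, high -3; BMI overweight 2, obese 5; fish
#' intake -3/-4/-5 across the published serving bands; and, under the
#' `original` adaptation only, cognitively stimulating activity (moderate
#' -6, high -7) and pesticide exposure (2).
#'
#' The `rotterdam` adaptation (default) reflects application to a cohort
#' without pesticide-exposure or cognitive-activity measurements: those two
#' items are dropped and the social-network item is derived from a 3-domain
#' composite ([social_network_composite()]) instead of the original
#' five-domain instrument. The `original` adaptation requires extra columns
#' `cognitive_activity` (`low`/`moderate`/`high`) and `pesticide_exposure`
#' (logical) and uses the `social_engagement` column directly.
#'
#' @param cohort A cohort data frame.
#' @param adaptation `"rotterdam"` (default) or `"original"`.
#' @param age_grid Age-by-sex point grid.
#' @param education_points Points for `<8`, `8-11`, `>11` years.
#' @param high_cholesterol_threshold mmol/L above which the high-cholesterol
#'   item applies.
#' @param activity_cutpoints Two MET-hours/week cutpoints splitting
#'   low/medium/high leisure activity.
#' @return A `score_components` data frame (`age_points` is the age-by-sex
#'   grid component).
#' @export
anu_adri_score <- function(cohort,
                           adaptation = c("rotterdam", "original"),
                           age_grid = anu_default_age_grid(),
                           education_points = c(low = 0, mid = 3, high = 6),
                           high_cholesterol_threshold = 6.5,
                           activity_cutpoints = c(50, 100)) {
  adaptation <- match.arg(adaptation)
  base_fields <- c("age", "sex", "education_years", "diabetes", "head_trauma",
                   "depressive_symptoms", "total_cholesterol", "smoking",
                   "alcohol_user", "heavy_drinking",
                   "physical_activity_met_hours", "bmi", "fish_servings_week")
  soc_fields <- if (adaptation == "rotterdam")
    c("living_with_partner", "married", "lonely") else "social_engagement"
  if (adaptation == "original" &&
      !all(c("cognitive_activity", "pesticide_exposure") %in% names(cohort)))
    stop("ANU-ADRI: 'original' adaptation requires cognitive_activity and ",
         "pesticide_exposure columns")
  extra_fields <- if (adaptation == "original")
    c("cognitive_activity", "pesticide_exposure") else character(0)
  require_fields(cohort, c(base_fields, soc_fields, extra_fields), "ANU-ADRI")

  age_pts <- anu_age_points(cohort$age, as.character(cohort$sex), age_grid)
  edu <- floor(cohort$education_years)
  edu_pts <- ifelse(edu > 11, education_points[["high"]],
                    ifelse(edu >= 8, education_points[["mid"]],
                           education_points[["low"]]))
  social <- if (adaptation == "rotterdam")
    social_network_composite(cohort$living_with_partner, cohort$married,
                             cohort$lonely)
  else cohort$social_engagement
  soc_pts <- c(high = 0, medium_high = 1, medium_low = 4,
               low = 6)[as.character(social)]
  smoke_pts <- c(never = 0, former = 1, current = 4)[as.character(cohort$smoking)]
  alc_pts <- ifelse(cohort$alcohol_user & !cohort$heavy_drinking, -3, 0)
  act <- cohort$physical_activity_met_hours
  act_pts <- ifelse(act > activity_cutpoints[2], -3,
                    ifelse(act >= activity_cutpoints[1], -2, 0))
  bmi_pts <- ifelse(cohort$bmi >= 30, 5, ifelse(cohort$bmi >= 25, 2, 0))
  fish_pts <- c(le_0.25 = 0, `0.26_2.0` = -3, `2.1_4.0` = -4,
                ge_4.1 = -5)[as.character(cohort$fish_servings_week)]
  total <- age_pts + edu_pts +
    cohort$diabetes * 3 + cohort$head_trauma * 4 +
    cohort$depressive_symptoms * 2 +
    (cohort$total_cholesterol > high_cholesterol_threshold) * 3 +
    soc_pts + smoke_pts + alc_pts + act_pts + bmi_pts + fish_pts
  if (adaptation == "original") {
    cog_pts <- c(low = 0, moderate = -6, high = -7)[as.character(cohort$cognitive_activity)]
    total <- total + cog_pts + cohort$pesticide_exposure * 2
  }
  score_components("ANU_ADRI", as.numeric(total), as.numeric(age_pts))
}
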