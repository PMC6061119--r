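#' Dementia Risk Score (DRS) equation objects
#'
#' The DRS is a regression model from UK primary-care records predicting
#' 5-year dementia risk, with separate equations for ages 60-79 and 80-95.
#' The 60-79 equation is bundled with its published coefficients, centering
#' constants (age 65.608, BMI 27.501, calendar year 2003.719) and 5-year
#' baseline survival S = 0.9969. The 80-95 equation was published only in
#' supplementary material and is not bundled; supply it via
#' `drs_equation("80_95", coefficients = ..., ...)` or
#' [read_drs_equation()]. An 80-95 equation may include an `anxiety` term
#' (operationalised downstream as anxiolytic-drug use).
#'
#' @param age_band `"60_79"` or `"80_95"`.
#' @param coefficients Named numeric vector; required for `"80_95"`.
#'   Recognised names: `age`, `age_sq`, `bmi`, `bmi_sq`, `female`,
#'   `hypertension`, `year`, `depq2`..`depq5`, `smoke_former`,
#'   `smoke_current`, `heavy_drinking`, `depression`, `aspirin`,
#'   `stroke_tia`, `af`, `diabetes`, `anxiety`.
#' @param centering Named list with `age`, `bmi`, `year`.
#' @param baseline_survival 5-year baseline survival in (0, 1).
#' @return A list of class `"drs_equation"`.
#' @export
drs_equation <- function(age_band = c("60_79", "80_95"),
                         coefficients = NULL,
                         centering = list(age = 65.608, bmi = 27.501,
                                          year = 2003.719),
                         baseline_survival = 0.9969) {
  age_band <- match.arg(age_band)
  if (is.null(coefficients)) {
    if (age_band != "60_79")
      stop("only the 60-79 DRS coefficients are bundled; supply the 80-95 ",
           "coefficients explicitly")
    coefficients <- c(
      age = 0.20921, age_sq = -0.00339,
      bmi = -0.0616, bmi_sq = 0.002508,
      female = 0.12854, hypertension = 0.13199,
      year = 0.04477,
      depq2 = 0.013371, depq3 = 0.117904, depq4 = 0.201776, depq5 = 0.225529,
      smoke_former = -0.06792, smoke_current = -0.08657,
      heavy_drinking = 0.443535,
      depression = 0.833612,
      aspirin = 0.252833,
      stroke_tia = 0.577207,
      af = 0.220728,
      diabetes = 0.286701)
  }
  if (any(!is.finite(coefficients))) stop("DRS coefficients must be finite")
  if (baseline_survival <= 0 || baseline_survival >= 1)
    stop("baseline_survival must be in (0, 1)")
  structure(list(age_band = age_band, coefficients = coefficients,
                 centering = centering, baseline_survival = baseline_survival),
            class = "drs_equation")
}

#' Read a DRS equation from a YAML config file
#'
#' Expects keys `age_band`, `coefficients` (a map), optional `centering`
#' and `baseline_survival`, so that supplementary-only coefficient sets can
#' be supplied without code changes.
#'
#' @param path YAML file path.
#' @return A `drs_equation` object.
#' @export
read_drs_equation <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading DRS equations from YAML requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  drs_equation(age_band = y$age_band,
               coefficients = unlist(y$coefficients),
               centering = if (!is.null(y$centering)) y$centering else
                 list(age = 65.608, bmi = 27.501, year = 2003.719),
               baseline_survival = if (!is.null(y$baseline_survival))
                 y$baseline_survival else 0.9969)
}

#' Household-composition deprivation quintile
#'
#' Emulates an area-deprivation index (used by the DRS in its development
#' data) with a composite of living status, marital status and loneliness:
#' the count of adverse states (not living with a partner, not married,
#' lonely) is mapped monotonically onto quintiles. The default mapping
#' `0 -> 1, 1 -> 2, 2 -> 4, 3 -> 5` leaves quintile 3 for configured
#' intermediate weightings.
#'
#' @param living_with_partner,married,lonely Logical vectors (no missing
#'   values).
#' @param mapping Integer vector of length 4 mapping adverse counts 0-3 to
#'   quintiles.
#' @return Integer vector of quintiles in 1..5.
#' @export
deprivation_quintile <- function(living_with_partner, married, lonely,
                                 mapping = c(1L, 2L, 4L, 5L)) {
  if (anyNA(living_with_partner) || anyNA(married) || anyNA(lonely))
    stop("deprivation_quintile: missing input")
  stopifnot(length(mapping) == 4, all(mapping %in% 1:5),
            !is.unsorted(mapping))
  k <- (!living_with_partner) + (!married) + lonely
  mapping[k + 1]
}

#' DRS linear predictor
#'
#' Evaluates the published polynomial-plus-indicator sum for each
#' participant: centered linear and quadratic age and BMI terms, female sex,
#' hypertension, centered calendar year, deprivation-quintile indicators,
#' smoking status, heavy drinking, depression (depressive symptoms or
#' antidepressant use), aspirin use, history of stroke or TIA, atrial
#' fibrillation and diabetes. Hypertension is operationalised as systolic
#' blood pressure over 140 mmHg or antihypertensive use. If the equation
#' carries an `anxiety` coefficient it is applied to anxiolytic-drug use.
#'
#' Ages below 60 fall outside both published bands; the predictor is still
#' computed (with a warning) and the pipeline decides usage.
#'
#' @param cohort A cohort data frame.
#' @param eq A [drs_equation()].
#' @return Numeric vector of linear-predictor values (0 at the reference
#'   profile).
#' @examples
#' ref <- data.frame(age = 65.608, bmi = 27.501, sex = "male", sbp = 120,
#'   uses_antihypertensives = FALSE, calendar_year = 2003.719,
#'   living_with_partner = TRUE, married = TRUE, lonely = FALSE,
#'   smoking = "never", heavy_drinking = FALSE, depressive_symptoms = FALSE,
#'   uses_antidepressants = FALSE, uses_aspirin = FALSE, stroke = FALSE,
#'   tia = FALSE, atrial_fibrillation = FALSE, diabetes = FALSE,
#'   uses_anxiolytics = FALSE)
#' drs_linear_predictor(ref, drs_equation())  # 0
#' @export
drs_linear_predictor <- function(cohort, eq = drs_equation()) {
  stopifnot(inherits(eq, "drs_equation"))
  fields <- c("age", "bmi", "sex", "sbp", "uses_antihypertensives",
              "calendar_year", "living_with_partner", "married", "lonely",
              "smoking", "heavy_drinking", "depressive_symptoms",
              "uses_antidepressants", "uses_aspirin", "stroke", "tia",
              "atrial_fibrillation", "diabetes")
  if ("anxiety" %in% names(eq$coefficients))
    fields <- c(fields, "uses_anxiolytics")
  require_fields(cohort, fields, "DRS")
  if (any(cohort$age < 60))
    warning("DRS applied below age 60, outside both published age bands")
  b <- function(nm) if (nm %in% names(eq$coefficients)) eq$coefficients[[nm]] else 0
  da <- cohort$age - eq$centering$age
  db <- cohort$bmi - eq$centering$bmi
  q <- deprivation_quintile(cohort$living_with_partner, cohort$married,
                            cohort$lonely)
  p <- b("age") * da + b("age_sq") * da^2 +
    b("bmi") * db + b("bmi_sq") * db^2 +
    b("female") * (cohort$sex == "female") +
    b("hypertension") * (cohort$sbp > 140 | cohort$uses_antihypertensives) +
    b("year") * (cohort$calendar_year - eq$centering$year) +
    b("depq2") * (q == 2) + b("depq3") * (q == 3) +
    b("depq4") * (q == 4) + b("depq5") * (q == 5) +
    b("smoke_former") * (cohort$smoking == "former") +
    b("smoke_current") * (cohort$smoking == "current") +
    b("heavy_drinking") * cohort$heavy_drinking +
    b("depression") * (cohort$depressive_symptoms | cohort$uses_antidepressants) +
    b("aspirin") * cohort$uses_aspirin +
    b("stroke_tia") * (cohort$stroke | cohort$tia) +
    b("af") * cohort$atrial_fibrillation +
    b("diabetes") * cohort$diabetes
  if ("anxiety" %in% names(eq$coefficients))
    p <- p + b("anxiety") * cohort$uses_anxiolytics
  as.numeric(p)
}

#' DRS age component of the linear predictor
#'
#' The centered linear + quadratic age terms only; used for the age-only
#' and without-age validation variants.
#'
#' @inheritParams drs_linear_predictor
#' @return Numeric vector.
#' @export
drs_age_component <- function(cohort, eq = drs_equation()) {
  b <- function(nm) if (nm %in% names(eq$coefficients)) eq$coefficients[[nm]] else 0
  da <- cohort$age - eq$centering$age
  as.numeric(b("age") * da + b("age_sq") * da^2)
}

#' Absolute 5-year risk from a DRS linear predictor
#'
#' `100 * (1 - S^exp(P))` with `S` the equation's baseline survival:
#' percent risk, strictly increasing in `P`, bounded in (0, 100).
#'
#' @param P Numeric linear-predictor values.
#' @param eq A [drs_equation()].
#' @return Percent risk.
#' @examples
#' drs_risk(0)  # 100 * (1 - 0.9969) = 0.31
#' @export
drs_risk <- function(P, eq = drs_equation()) {
  stopifnot(all(is.finite(P)))
  100 * (1 - eq$baseline_survival^exp(P))
}

#' Select the DRS equation for a participant's age
#'
#' Ages under 80 use the 60-79 equation, ages 80 and over the 80-95
#' equation when one is configured (the half-open boundary closes the
#' published gap between "below 79" and "above 80" in favour of the young
#' equation's centering). If no 80-95 equation is available the young
#' equation is used for everyone, with a warning.
#'
#' @param age Numeric vector of ages.
#' @param registry List with elements `young` (required) and optional `old`.
#' @return List with `eq` (list of the two equations, `old` possibly
#'   `NULL`) and `use_old` (logical vector per participant).
#' @export
drs_select_equation <- function(age, registry = list(young = drs_equation(),
                                                     old = NULL)) {
  if (is.null(registry$young)) stop("DRS registry must hold the 60-79 equation")
  use_old <- age >= 80
  if (any(use_old) && is.null(registry$old)) {
    warning("no 80-95 DRS equation configured; using the 60-79 equation ",
            "for participants aged 80+")
    use_old <- rep(FALSE, length(age))
  }
  list(registry = registry, use_old = use_old)
}

#' Stitched DRS scoring across the full age range
#'
#' Applies [drs_select_equation()] row-wise: the 60-79 equation below 80,
#' the 80-95 equation (when configured) at 80 and over, as in validation
#' across an age range wider than either equation's design population.
#'
#' @param cohort A cohort data frame.
#' @param registry As in [drs_select_equation()].
#' @return A `score_components` data frame; `total` is the linear
#'   predictor, `age_points` its age component, `predicted_risk` the
#'   absolute 5-year risk as a proportion in (0, 1).
#' @export
drs_score <- function(cohort, registry = list(young = drs_equation(),
                                              old = NULL)) {
  sel <- drs_select_equation(cohort$age, registry)
  lp <- age_lp <- risk <- numeric(nrow(cohort))
  for (old in unique(sel$use_old)) {
    idx <- sel$use_old == old
    eq <- if (old) sel$registry$old else sel$registry$young
    lp[idx] <- drs_linear_predictor(cohort[idx, , drop = FALSE], eq)
    age_lp[idx] <- drs_age_component(cohort[idx, , drop = FALSE], eq)
    risk[idx] <- drs_risk(lp[idx], eq) / 100
  }
  score_components("DRS", lp, age_lp, predicted_risk = risk)
}
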