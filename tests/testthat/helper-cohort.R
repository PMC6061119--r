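# A single-row cohort at the reference profile of every scorer; override
# fields per test. Values are chosen so each model's reference score is 0
# (DRS centering constants; CAIDE/BDSI/ANU zero-point categories).
ref_participant <- function(...) {
  p <- data.frame(
    id = "ref", wave = factor("original", c("original", "extended")),
    age = 65.608, sex = factor("male", c("female", "male")),
    education_years = 12, sbp = 120, bmi = 27.501, total_cholesterol = 5,
    hdl_cholesterol = 1.4, physical_activity_met_hours = 77,
    active_minutes_met4 = 60,
    diabetes = FALSE, stroke = FALSE, tia = FALSE,
    atrial_fibrillation = FALSE, head_trauma = FALSE,
    depressive_symptoms = FALSE, needs_help_finances_medications = FALSE,
    smoking = factor("never", c("never", "former", "current")),
    alcohol_user = FALSE, heavy_drinking = FALSE,
    social_engagement = factor("high",
      c("high", "medium_high", "medium_low", "low")),
    living_with_partner = TRUE, married = TRUE, lonely = FALSE,
    fish_servings_week = factor("le_0.25",
      c("le_0.25", "0.26_2.0", "2.1_4.0", "ge_4.1")),
    uses_antihypertensives = FALSE, uses_anxiolytics = FALSE,
    uses_aspirin = FALSE, uses_antidepressants = FALSE, uses_nsaids = FALSE,
    calendar_year = 2003.719, time = 10,
    event = factor("censored", c("censored", "dementia")),
    death = FALSE, ad_subtype = NA, stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) {
    if (is.factor(p[[nm]])) p[[nm]] <- factor(args[[nm]], levels(p[[nm]]))
    else p[[nm]] <- args[[nm]]
  }
  p
}

# Small complete synthetic cohort for scoring/pipeline tests
small_cohort <- function(n = 400, seed = 1, missingness = FALSE, ...) {
  n_o <- round(n * 3983 / 6667)
  cfg <- generator_config(n_original = n_o, n_extended = n - n_o,
                          seed = seed, ...)
  generate_cohort(cfg, missingness = missingness)
}
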