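test_that("CAIDE scores the published point categories", {
  # all zero-point categories
  p0 <- ref_participant(age = 45, sex = "female", education_years = 12,
                        sbp = 130, bmi = 24, total_cholesterol = 5,
                        active_minutes_met4 = 60)
  expect_identical(caide_score(p0)$total, 0)

  # every deleterious category at once: 4+1+3+2+2+2+1 = 15
  p15 <- ref_participant(age = 60, sex = "male", education_years = 5,
                         sbp = 150, bmi = 31, total_cholesterol = 7,
                         active_minutes_met4 = 10,
                         physical_activity_met_hours = 1)
  expect_identical(caide_score(p15)$total, 15)

  # age band edges: 47 falls in the middle band
  expect_identical(caide_score(ref_participant(age = 47))$age_points, 3)
  expect_identical(caide_score(ref_participant(age = 53))$age_points, 3)
  expect_identical(caide_score(ref_participant(age = 53.5))$age_points, 4)
  expect_identical(caide_score(ref_participant(age = 46.9))$age_points, 0)

  # strict inequalities at the clinical cutoffs: ties take the lower points
  at_cut <- ref_participant(sex = "female", sbp = 140, bmi = 30,
                            total_cholesterol = 6.5)
  expect_identical(caide_score(at_cut)$non_age_points, 0)

  # missing required input errors and names the field
  p_na <- ref_participant(); p_na$sbp <- NA_real_
  expect_error(caide_score(p_na), "sbp")
})

test_that("the CAIDE inactivity rule uses minutes at MET >= 4 with a MET-hours fallback", {
  active <- ref_participant(active_minutes_met4 = 40)
  inactive <- ref_participant(active_minutes_met4 = 39.9)
  expect_identical(caide_score(active)$total, caide_score(inactive)$total - 1)
  fallback <- ref_participant(sex = "female", physical_activity_met_hours = 2)
  fallback$active_minutes_met4 <- NA_real_
  expect_identical(caide_score(fallback)$non_age_points, 1)
})

test_that("BDSI scores the published points with a 65-anchored age slope", {
  expect_identical(bdsi_score(ref_participant(age = 65))$total, 0)
  p <- ref_participant(age = 70, diabetes = TRUE, stroke = TRUE)
  expect_identical(bdsi_score(p)$total, 5 + 3 + 6)
  full <- ref_participant(age = 70, education_years = 11, bmi = 18,
                          diabetes = TRUE, stroke = TRUE,
                          needs_help_finances_medications = TRUE,
                          depressive_symptoms = TRUE)
  expect_identical(bdsi_score(full)$non_age_points, 42)
  # extrapolation: 1 point/year continues outside 65-79
  expect_error(bdsi_score(ref_participant(age = 85)), "65-79")
  expect_identical(bdsi_score(ref_participant(age = 85),
                              extrapolate_age = TRUE)$age_points, 20)
  expect_identical(bdsi_score(ref_participant(age = 60),
                              extrapolate_age = TRUE)$age_points, -5)
})

test_that("ANU-ADRI sums the published item points under the 3-domain adaptation", {
  # reference man under 65 with low education band, low activity: all items zero
  base <- ref_participant(age = 60, education_years = 7, bmi = 24,
                          physical_activity_met_hours = 20)
  expect_identical(anu_adri_score(base)$total, 0)

  # protective items: light-moderate alcohol, high activity, fish 2.1-4.0
  prot <- ref_participant(age = 60, education_years = 7, bmi = 24,
                          alcohol_user = TRUE,
                          physical_activity_met_hours = 150,
                          fish_servings_week = "2.1_4.0")
  expect_identical(anu_adri_score(prot)$total, -3 - 3 - 4)

  # deleterious items add the printed points over the reference
  del <- ref_participant(age = 60, education_years = 7, bmi = 24,
                         physical_activity_met_hours = 20,
                         smoking = "current", diabetes = TRUE,
                         depressive_symptoms = TRUE)
  expect_identical(anu_adri_score(del)$total - anu_adri_score(base)$total,
                   4 + 3 + 2)

  # age-sex grid endpoints as published
  expect_identical(anu_adri_score(ref_participant(age = 60))$age_points, 0)
  expect_identical(
    anu_adri_score(ref_participant(age = 93, sex = "female"))$age_points, 41)

  # social network via the household composite
  low_soc <- ref_participant(age = 60, education_years = 7, bmi = 24,
                             physical_activity_met_hours = 20,
                             living_with_partner = FALSE,
                             married = FALSE, lonely = TRUE)
  expect_identical(anu_adri_score(low_soc)$total, 6)

  # original adaptation needs the unmeasured fields
  expect_error(anu_adri_score(base, adaptation = "original"),
               "cognitive_activity")
  orig <- cbind(base, cognitive_activity = "high", pesticide_exposure = TRUE)
  expect_identical(anu_adri_score(orig, adaptation = "original")$total, -7 + 2)
})

test_that("the DRS linear predictor reproduces the published equation term by term", {
  eq <- drs_equation()
  ref <- ref_participant()
  expect_equal(drs_linear_predictor(ref, eq), 0, tolerance = 1e-12)
  # single-term activations against the printed coefficients
  expect_equal(drs_linear_predictor(ref_participant(stroke = TRUE), eq),
               0.577207, tolerance = 1e-12)
  expect_equal(drs_linear_predictor(ref_participant(tia = TRUE), eq),
               0.577207, tolerance = 1e-12)
  expect_equal(drs_linear_predictor(ref_participant(calendar_year = 2004.719), eq),
               0.04477, tolerance = 1e-12)
  expect_equal(drs_linear_predictor(ref_participant(sex = "female"), eq),
               0.12854, tolerance = 1e-12)
  expect_equal(drs_linear_predictor(ref_participant(uses_antidepressants = TRUE), eq),
               0.833612, tolerance = 1e-12)
  expect_equal(drs_linear_predictor(ref_participant(depressive_symptoms = TRUE), eq),
               0.833612, tolerance = 1e-12)
  # hypertension via pressure or medication
  expect_equal(drs_linear_predictor(ref_participant(sbp = 141), eq),
               0.13199, tolerance = 1e-12)
  expect_equal(drs_linear_predictor(ref_participant(uses_antihypertensives = TRUE), eq),
               0.13199, tolerance = 1e-12)
  # quadratic age term: age 70 -> 0.20921*da - 0.00339*da^2
  da <- 70 - 65.608
  expect_equal(drs_linear_predictor(ref_participant(age = 70), eq),
               0.20921 * da - 0.00339 * da^2, tolerance = 1e-12)
  expect_warning(drs_linear_predictor(ref_participant(age = 58), eq), "60")
})

test_that("DRS risk transform and equation selection behave as published", {
  expect_equal(drs_risk(0), 100 * (1 - 0.9969), tolerance = 1e-12)
  expect_equal(drs_risk(-50), 0, tolerance = 1e-6)
  p <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(drs_risk(p)) > 0))
  expect_true(all(drs_risk(p) > 0 & drs_risk(p) < 100))

  sel <- drs_select_equation(c(70, 79.5), list(young = drs_equation(), old = NULL))
  expect_identical(sel$use_old, c(FALSE, FALSE))
  old_eq <- drs_equation("80_95", coefficients = c(age = 0.1))
  sel2 <- drs_select_equation(c(70, 85), list(young = drs_equation(), old = old_eq))
  expect_identical(sel2$use_old, c(FALSE, TRUE))
  expect_warning(drs_select_equation(85, list(young = drs_equation(), old = NULL)),
                 "80-95")
  expect_error(drs_select_equation(70, list(young = NULL)), "registry")
})

test_that("the deprivation composite maps adverse counts to quintiles", {
  expect_identical(deprivation_quintile(TRUE, TRUE, FALSE), 1L)
  expect_identical(deprivation_quintile(FALSE, TRUE, FALSE), 2L)
  expect_identical(deprivation_quintile(FALSE, FALSE, FALSE), 4L)
  expect_identical(deprivation_quintile(FALSE, FALSE, TRUE), 5L)
  expect_identical(deprivation_quintile(TRUE, FALSE, TRUE), 4L)
  expect_error(deprivation_quintile(NA, TRUE, FALSE), "missing")
})

test_that("variant decomposition, monotonicity and bounds hold over random cohorts", {
  co <- small_cohort(n = 300, seed = 21)
  for (m in c("caide", "bdsi", "anu_adri", "drs")) {
    full <- score_variant(co, m, "full")
    age <- score_variant(co, m, "age_only")
    without <- score_variant(co, m, "without_age")
    expect_equal(as.numeric(age) + as.numeric(without), as.numeric(full),
                 tolerance = 1e-12, label = m)
  }
  expect_true(all(score_variant(co, "caide", "full") >= 0))
  expect_true(all(score_variant(co, "caide", "full") <= 15))
  expect_true(all(score_variant(co, "bdsi", "without_age") >= 0))
  expect_true(all(score_variant(co, "bdsi", "without_age") <= 42))
  risks <- attr(score_variant(co, "drs", "full"), "components")$predicted_risk
  expect_true(all(risks > 0 & risks < 1))

  # deleterious single items never decrease the total
  base <- ref_participant(age = 70)
  for (fld in c("diabetes", "stroke", "depressive_symptoms",
                "needs_help_finances_medications")) {
    worse <- base; worse[[fld]] <- TRUE
    expect_gte(bdsi_score(worse)$total, bdsi_score(base)$total)
    expect_gte(suppressWarnings(drs_score(worse))$total,
               suppressWarnings(drs_score(base))$total)
    expect_gte(anu_adri_score(worse)$total, anu_adri_score(base)$total)
  }
  # protective ANU-ADRI items never increase it
  better <- base; better$alcohol_user <- TRUE
  expect_lte(anu_adri_score(better)$total, anu_adri_score(base)$total)
  fishy <- base; fishy$fish_servings_week <- factor("ge_4.1",
    levels(base$fish_servings_week))
  expect_lte(anu_adri_score(fishy)$total, anu_adri_score(base)$total)

  # row independence: shuffling rows shuffles scores identically
  perm <- sample(nrow(co))
  expect_equal(as.numeric(score_variant(co[perm, ], "anu_adri", "full")),
               as.numeric(score_variant(co, "anu_adri", "full"))[perm],
               tolerance = 1e-12)
})

test_that("CAIDE age component degenerates in an all-elderly cohort", {
  co <- small_cohort(n = 120, seed = 9)
  expect_true(all(co$age > 53))
  expect_true(attr(score_variant(co, "caide", "age_only"), "degenerate"))
  expect_false(attr(score_variant(co, "caide", "full"), "degenerate"))
})
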