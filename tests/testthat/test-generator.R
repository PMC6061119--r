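test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_original = 120, n_extended = 80, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a, c2))
})

test_that("degenerate sizes and invalid configs are handled", {
  cfg <- generator_config(n_original = 0, n_extended = 0)
  expect_identical(nrow(generate_cohort(cfg)), 0L)
  expect_error(generator_config(dementia_hazard = list(rate = -1, shape = 0.1,
                                                       ref_age = 70)),
               "rate")
  bad <- generator_config()
  bad$missingness$bmi$rate <- 1.5
  expect_error(validate_generator_config(bad), "missingness")
})

test_that("generated covariate marginals match the configured Table-1 values", {
  cfg <- generator_config(seed = 8, missingness = list())
  set.seed(8)
  co <- generate_covariates(cfg)
  n <- nrow(co)
  # per-wave means of age against the analytic truncated-normal expectation
  tn_mean <- function(mu, sd, lo) {
    a <- (lo - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  for (w in c("original", "extended")) {
    am <- cfg$age_model[[w]]
    idx <- co$wave == w
    expect_lt(abs(mean(co$age[idx]) - tn_mean(am$mean, am$sd, am$min)),
              3 * sd(co$age[idx]) / sqrt(sum(idx)))
  }
  # binary prevalences (3 sigma Monte-Carlo band), per wave
  for (nm in c("diabetes", "stroke", "needs_help_finances_medications",
               "uses_aspirin", "lonely")) {
    p <- cfg$covariate_params[[nm]]
    for (w in c("original", "extended")) {
      idx <- co$wave == w
      target <- p$prev[[w]]
      expect_lt(abs(mean(co[[nm]][idx]) - target),
                3 * sqrt(target * (1 - target) / sum(idx)), label = nm)
    }
  }
  expect_lt(abs(mean(co$sex == "female") -
                (0.579 * 3983 + 0.552 * 2684) / 6667), 3 * 0.5 / sqrt(n))
  # continuous means
  for (nm in c("bmi", "sbp", "education_years", "total_cholesterol")) {
    p <- cfg$covariate_params[[nm]]
    for (w in c("original", "extended")) {
      idx <- co$wave == w
      expect_lt(abs(mean(co[[nm]][idx]) - p$mean[[w]]),
                3.5 * p$sd[[w]] / sqrt(sum(idx)), label = nm)
    }
  }
  # categorical level frequencies
  sm <- cfg$covariate_params$smoking
  for (w in c("original", "extended")) {
    idx <- co$wave == w
    obs <- as.vector(table(co$smoking[idx]) / sum(idx))
    expect_lt(max(abs(obs - sm$prob[[w]])), 3.5 * 0.5 / sqrt(sum(idx)))
  }
})

test_that("outcome generation follows the configured hazards", {
  # no dementia hazard, no dementia events
  cfg0 <- generator_config(n_original = 150, n_extended = 100, seed = 4,
                           dementia_hazard = list(rate = 0, shape = 0.1,
                                                  ref_age = 70),
                           missingness = list())
  co0 <- generate_cohort(cfg0)
  expect_identical(sum(co0$event == "dementia"), 0L)

  # death and administrative censoring pushed out: everyone develops dementia
  cfg1 <- generator_config(n_original = 150, n_extended = 100, seed = 4,
                           death_hazard = list(rate = 0, shape = 0.1, ref_age = 70),
                           end_year = 1e6, missingness = list())
  co1 <- generate_cohort(cfg1)
  expect_true(all(co1$event == "dementia"))

  # constant hazard: crude incidence is the hazard itself (in events/1000 py)
  lam <- 0.02
  cfgc <- generator_config(n_original = 3000, n_extended = 2000, seed = 12,
                           dementia_hazard = list(rate = lam, shape = 0,
                                                  ref_age = 70),
                           death_hazard = list(rate = 0, shape = 0, ref_age = 70),
                           missingness = list())
  coc <- generate_cohort(cfgc)
  rate <- incidence_rate(coc)
  se <- 1000 * lam / sqrt(sum(coc$event == "dementia"))
  expect_lt(abs(rate - 1000 * lam), 3 * se)
})

test_that("missingness injection masks at the configured rates and waves", {
  cfg <- generator_config(n_original = 1200, n_extended = 800, seed = 6)
  co <- generate_cohort(cfg, missingness = FALSE)
  expect_false(anyNA(co$bmi))

  set.seed(1)
  masked <- inject_missingness(co, cfg)
  # wave-structured: head trauma gone for the whole extended wave
  expect_true(all(is.na(masked$head_trauma[masked$wave == "extended"])))
  frac <- mean(is.na(masked$head_trauma))
  expect_lt(abs(frac - (800 / 2000 + 0.011 * 1200 / 2000)), 0.02)
  # outcome fields never masked
  expect_false(anyNA(masked$time))
  expect_false(anyNA(masked$event))

  cfg$missingness <- list(bmi = list(rate = 1.0, missing_wave = NULL))
  set.seed(2)
  all_bmi <- inject_missingness(co, cfg)
  expect_true(all(is.na(all_bmi$bmi)))
  expect_false(anyNA(all_bmi$sbp))
})

test_that("true_risk matches closed forms and numerical quadrature", {
  co <- ref_participant(age = 72, diabetes = TRUE,
                        smoking = "current")
  cfg <- generator_config()

  cfg0 <- cfg; cfg0$dementia_hazard$rate <- 0
  expect_identical(true_risk(co, cfg0, 10), 0)

  # constant-hazard closed form
  cfgc <- cfg
  cfgc$dementia_hazard <- list(rate = 0.03, shape = 0, ref_age = 70)
  expect_equal(true_risk(co, cfgc, 7), 1 - exp(-0.03 * 7), tolerance = 1e-12)

  # Gompertz with covariate effects against quadrature of the hazard
  h <- function(t) {
    dh <- cfg$dementia_hazard
    lp <- dh$log_hr[["diabetes"]] + dh$log_hr[["smoking:current"]] +
      dh$log_hr[["education_years"]] * co$education_years +
      dh$log_hr[["physical_activity_met_hours"]] * co$physical_activity_met_hours +
      dh$log_hr[["total_cholesterol"]] * co$total_cholesterol +
      dh$log_hr[["living_with_partner"]] +
      dh$log_hr[["fish_servings_week:le_0.25"]]
    dh$rate * exp(lp + dh$shape * (co$age + t - dh$ref_age))
  }
  H <- integrate(h, 0, 10, rel.tol = 1e-12)$value
  expect_equal(true_risk(co, cfg, 10), 1 - exp(-H), tolerance = 1e-8)

  expect_error(true_risk(co, cfg, 0), "horizon")
})

test_that("generator configurations load from YAML overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_original: 30",
    "n_extended: 20",
    "seed: 5",
    "dementia_hazard:",
    "  rate: 0.01",
    "  log_hr:",
    "    diabetes: 0.5"), path)
  cfg <- read_generator_config(path)
  expect_identical(cfg$n_total, 50L)
  expect_identical(cfg$dementia_hazard$rate, 0.01)
  expect_identical(cfg$dementia_hazard$log_hr, c(diabetes = 0.5))
  # untouched defaults survive the merge
  expect_identical(cfg$dementia_hazard$shape, 0.126)
  expect_identical(cfg$age_model$extended$min, 55)
  writeLines("bogus_key: 1", path)
  expect_error(read_generator_config(path), "unknown configuration")
})
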