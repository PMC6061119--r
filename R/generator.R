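#' Default covariate marginal parameters for the synthetic cohort
#'
#' One entry per covariate, with per-wave marginal parameters (means/SDs for
#' continuous variables, prevalences for binary, level probabilities for
#' categorical) mirroring the baseline table of the emulated two-wave Dutch
#' cohort, plus an age slope linking each covariate to baseline age. Binary
#' slopes are on the log-odds scale per year of age; continuous slopes are in
#' the covariate's units per year. Intercepts are re-solved against the
#' realized age draw at generation time, so the configured marginal is
#' matched in expectation whatever the slope.
#'
#' Waves are named `original` (third examination round of the initial
#' cohort, 1997-1999, ages 61.5+) and `extended` (first round of the
#' extension cohort, 2000-2001, ages 55+).
#'
#' @return A named list of per-covariate parameter lists.
#' @export
default_covariate_params <- function() {
  cont <- function(mean_o, mean_e, sd_o, sd_e, slope = 0, min = -Inf)
    list(type = "normal", mean = c(original = mean_o, extended = mean_e),
         sd = c(original = sd_o, extended = sd_e), age_slope = slope, min = min)
  bin <- function(p_o, p_e, slope = 0)
    list(type = "binary", prev = c(original = p_o, extended = p_e),
         age_slope = slope)
  cat_ <- function(levels, p_o, p_e)
    list(type = "categorical", levels = levels,
         prob = list(original = p_o / sum(p_o), extended = p_e / sum(p_e)))
  list(
    sex = bin(0.579, 0.552, 0.015), # prevalence of female
    bmi = cont(26.9, 27.3, 4.0, 4.0, slope = -0.053, min = 14),
    sbp = cont(144, 143, 21, 22, slope = 0.5, min = 80),
    education_years = cont(11.0, 12.2, 3.6, 3.5, slope = -0.18, min = 0),
    total_cholesterol = cont(5.8, 5.8, 0.98, 0.98, slope = -0.01, min = 2),
    hdl_cholesterol = cont(1.39, 1.37, 0.40, 0.37, min = 0.3),
    physical_activity_met_hours =
      list(type = "lognormal", meanlog = c(original = log(78), extended = log(75)),
           sdlog = c(original = 0.57, extended = 0.57), age_slope = -0.03),
    active_minutes_met4 =
      list(type = "derived_activity", ref_meanlog = log(60), sdlog = 1.0,
           met_hours_coupling = 0.3),
    diabetes = bin(0.110, 0.104, 0.07),
    stroke = bin(0.039, 0.033, 0.09),
    tia = bin(0.028, 0.031, 0.06),
    atrial_fibrillation = bin(0.064, 0.029, 0.11),
    head_trauma = bin(0.111, 0.111, 0),
    depressive_symptoms = bin(0.061, 0.099, 0.05),
    needs_help_finances_medications = bin(0.235, 0.091, 0.13),
    smoking = cat_(c("never", "former", "current"),
                   c(0.324, 0.490, 0.180), c(0.287, 0.473, 0.227)),
    alcohol_user = bin(0.815, 0.831, -0.05),
    heavy_drinking = bin(0.04, 0.04, -0.02),
    social_engagement = cat_(c("high", "medium_high", "medium_low", "low"),
                             c(0.000, 0.044, 0.735, 0.215),
                             c(0.007, 0.181, 0.708, 0.102)),
    living_with_partner = bin(0.70, 0.74, -0.07),
    married = bin(0.66, 0.70, -0.06),
    lonely = bin(0.09, 0.08, 0.06),
    fish_servings_week = cat_(c("le_0.25", "0.26_2.0", "2.1_4.0", "ge_4.1"),
                              c(0.4408, 0.5295, 0.0254, 0.0043),
                              c(0.4408, 0.5295, 0.0254, 0.0043)),
    uses_antihypertensives = bin(0.242, 0.219, 0.05),
    uses_anxiolytics = bin(0.136, 0.092, 0.058),
    uses_aspirin = bin(0.196, 0.141, 0.053),
    uses_antidepressants = bin(0.05, 0.06, 0),
    uses_nsaids = bin(0.083, 0.089, 0)
  )
}

#' Default missingness pattern
#'
#' Missing-completely-at-random rates per covariate, with wave-structured
#' total missingness for the two variables only measured in the original
#' wave (head trauma, fish intake). Rates follow the per-variable missing
#' fractions of the emulated baseline table.
#'
#' @return Named list; each element has `rate` (MCAR rate outside any
#'   fully-missing wave) and optional `missing_wave`.
#' @export
default_missingness <- function() {
  m <- function(rate, missing_wave = NULL) list(rate = rate, missing_wave = missing_wave)
  list(
    bmi = m(0.015), sbp = m(0.009), education_years = m(0.018),
    alcohol_user = m(0.010), smoking = m(0.009),
    total_cholesterol = m(0.041), hdl_cholesterol = m(0.052),
    physical_activity_met_hours = m(0.042), active_minutes_met4 = m(0.042),
    diabetes = m(0.073), stroke = m(0.010), tia = m(0.030),
    atrial_fibrillation = m(0.028), depressive_symptoms = m(0.042),
    social_engagement = m(0.004),
    needs_help_finances_medications = m(0.071),
    uses_antihypertensives = m(0.048),
    uses_antidepressants = m(0.02),
    living_with_partner = m(0.005), married = m(0.005), lonely = m(0.005),
    head_trauma = m(0.011, missing_wave = "extended"),
    fish_servings_week = m(0.129, missing_wave = "extended")
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the validation sample: 6667 participants in two
#' enrollment waves (3983 / 2684), per-wave truncated-normal baseline age
#' distributions, covariate marginals from the baseline table, an
#' attained-age Gompertz dementia hazard, a Gompertz hazard for
#' dementia-free death (treated as censoring downstream), administrative
#' censoring at the start of 2015, and wave-structured missingness.
#'
#' The per-wave age distributions are parameterised as a parent normal
#' `N(mean, sd)` left-truncated at `min`; the defaults were fitted once so
#' that the realized wave means (72.2 / 64.6 years), the overall mean
#' (69.1), and the fraction under 65 (37%) match the emulated sample. The
#' default hazards (`dementia_hazard`: rate 0.00483, shape 0.126 at
#' reference age 70; `death_hazard`: rate 0.021, shape 0.095) were
#' calibrated so the crude dementia incidence is about 11.5 per 1000
#' person-years and the median observed follow-up about 13.2 years.
#'
#' The hazard for a participant of baseline age `a` is
#' `h(t) = rate * exp(shape * (a + t - ref_age)) * exp(lp)` where `lp` is a
#' per-covariate log-hazard sum (`log_hr`). The default dementia hazard
#' carries small literature-plausible effects for diabetes, stroke,
#' depressive symptoms, needing help with finances/medications, head trauma,
#' atrial fibrillation and education, so that attained age dominates the
#' signal but established risk factors retain a marginal independent
#' contribution, as observed in the emulated study; scale `log_hr` up to
#' build scenarios where non-age predictors carry real added value.
#'
#' @param n_original,n_extended Per-wave sample sizes.
#' @param seed Integer seed used by [generate_cohort()].
#' @param age_model Per-wave list with `mean`, `sd`, `min` of the truncated
#'   parent normal.
#' @param covariate_params See [default_covariate_params()].
#' @param dementia_hazard,death_hazard Lists with `rate`, `shape`,
#'   `ref_age`, and optional named numeric `log_hr` (per-covariate extra
#'   log-hazard applied to the 0/1 or numeric covariate value).
#' @param exam_window Per-wave calendar interval from which the baseline
#'   examination date is drawn uniformly.
#' @param end_year Administrative censoring date (calendar years);
#'   per-participant administrative follow-up is `end_year` minus the exam
#'   date.
#' @param missingness See [default_missingness()]; set to `list()` to
#'   generate complete data.
#' @param p_ad_given_dementia Probability that a dementia event is
#'   Alzheimer's disease.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_original = 3983,
                             n_extended = 2684,
                             seed = 1L,
                             age_model = list(
                               original = list(mean = 62.7, sd = 12.7, min = 61.5),
                               extended = list(mean = 45.1, sd = 15.7, min = 55)),
                             covariate_params = default_covariate_params(),
                             dementia_hazard = list(
                               rate = 0.00483, shape = 0.126, ref_age = 70,
                               log_hr = c(diabetes = 0.14, stroke = 0.22,
                                          depressive_symptoms = 0.17,
                                          needs_help_finances_medications = 0.18,
                                          head_trauma = 0.22,
                                          atrial_fibrillation = 0.10,
                                          education_years = -0.05,
                                          alcohol_user = -0.25,
                                          lonely = 0.15,
                                          living_with_partner = -0.08,
                                          `smoking:current` = 0.45,
                                          `smoking:former` = 0.10,
                                          `fish_servings_week:le_0.25` = 0.22,
                                          physical_activity_met_hours = -0.002,
                                          total_cholesterol = 0.07)),
                             death_hazard = list(rate = 0.021, shape = 0.095,
                                                 ref_age = 70, log_hr = NULL),
                             exam_window = list(original = c(1997, 1999),
                                                extended = c(2000, 2002)),
                             end_year = 2015,
                             missingness = default_missingness(),
                             p_ad_given_dementia = 696 / 867) {
  cfg <- list(n_original = n_original, n_extended = n_extended,
              n_total = n_original + n_extended, seed = seed,
              age_model = age_model, covariate_params = covariate_params,
              dementia_hazard = dementia_hazard, death_hazard = death_hazard,
              exam_window = exam_window, end_year = end_year,
              missingness = missingness,
              p_ad_given_dementia = p_ad_given_dementia)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_original >= 0, cfg$n_extended >= 0,
            cfg$n_total == cfg$n_original + cfg$n_extended)
  for (h in list(cfg$dementia_hazard, cfg$death_hazard)) {
    if (!is.finite(h$rate) || h$rate < 0) stop("hazard rate must be finite and >= 0")
    if (!is.finite(h$shape)) stop("hazard shape must be finite")
  }
  if (cfg$p_ad_given_dementia < 0 || cfg$p_ad_given_dementia > 1)
    stop("p_ad_given_dementia must be a probability")
  for (nm in names(cfg$covariate_params)) {
    p <- cfg$covariate_params[[nm]]
    if (p$type == "binary" && any(p$prev < 0 | p$prev > 1))
      stop("prevalence outside [0,1] for ", nm)
    if (p$type == "categorical" &&
        any(vapply(p$prob, function(q) any(q < 0) || abs(sum(q) - 1) > 1e-8, TRUE)))
      stop("invalid level probabilities for ", nm)
  }
  for (nm in names(cfg$missingness)) {
    r <- cfg$missingness[[nm]]$rate
    if (r < 0 || r > 1) stop("missingness rate outside [0,1] for ", nm)
  }
  invisible(cfg)
}

# typed zero-row covariate frame matching the schema
empty_covariate_frame <- function() {
  s <- cohort_schema()
  s <- s[!s$name %in% c("time", "event", "death", "ad_subtype"), ]
  out <- lapply(seq_len(nrow(s)), function(i) {
    switch(s$type[i],
           id = character(0), real = numeric(0), bool = logical(0),
           cat = factor(character(0), levels = schema_levels(s[i, ])))
  })
  names(out) <- s$name
  as.data.frame(out, stringsAsFactors = FALSE)
}

r_truncnorm <- function(n, mean, sd, lo)
  qnorm(runif(n, pnorm(lo, mean, sd), 1), mean, sd)

# solve the logistic intercept so that mean(plogis(c + b*age)) hits `target`
# on the realized age vector
solve_logit_intercept <- function(age, slope, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(c0) mean(plogis(c0 + slope * age)) - target
  uniroot(f, c(-40, 40), tol = 1e-12)$root
}

#' Generate baseline covariates for a synthetic cohort
#'
#' Draws per-wave sample sizes exactly, ages from the configured truncated
#' normals, and covariates from their configured marginals with age links.
#' Deterministic given the RNG state; use [generate_cohort()] for a fully
#' seeded draw.
#'
#' @param config A [generator_config()].
#' @return A cohort data frame without outcome columns.
#' @export
generate_covariates <- function(config) {
  validate_generator_config(config)
  waves <- c(rep("original", config$n_original),
             rep("extended", config$n_extended))
  n <- length(waves)
  if (n == 0) return(empty_covariate_frame())
  age <- numeric(n)
  exam <- numeric(n)
  for (w in c("original", "extended")) {
    idx <- waves == w
    if (!any(idx)) next
    am <- config$age_model[[w]]
    age[idx] <- r_truncnorm(sum(idx), am$mean, am$sd, am$min)
    ew <- config$exam_window[[w]]
    exam[idx] <- runif(sum(idx), ew[1], ew[2])
  }
  out <- data.frame(id = sprintf("p%06d", seq_len(n)),
                    wave = factor(waves, levels = c("original", "extended")),
                    age = age, stringsAsFactors = FALSE)

  cp <- config$covariate_params
  for (nm in names(cp)) {
    p <- cp[[nm]]
    x <- rep(NA_real_, n)
    if (p$type == "normal") {
      for (w in c("original", "extended")) {
        idx <- waves == w
        if (!any(idx)) next
        b <- p$age_slope
        sd_resid <- sqrt(max(p$sd[[w]]^2 - b^2 * var(age[idx]),
                             (0.2 * p$sd[[w]])^2))
        x[idx] <- p$mean[[w]] + b * (age[idx] - mean(age[idx])) +
          rnorm(sum(idx), 0, sd_resid)
      }
      out[[nm]] <- pmax(x, p$min)
    } else if (p$type == "lognormal") {
      for (w in c("original", "extended")) {
        idx <- waves == w
        if (!any(idx)) next
        ml <- p$meanlog[[w]] + p$age_slope * (age[idx] - mean(age[idx]))
        x[idx] <- exp(rnorm(sum(idx), ml, p$sdlog[[w]]))
      }
      out[[nm]] <- x
    } else if (p$type == "derived_activity") {
      # weekly minutes of activity at MET >= 4, loosely coupled to total
      # leisure MET-hours; drives the CAIDE physical-inactivity item
      met <- out$physical_activity_met_hours
      ml <- p$ref_meanlog + p$met_hours_coupling * (log(met) - median(log(met)))
      out[[nm]] <- exp(rnorm(n, ml, p$sdlog))
    } else if (p$type == "binary") {
      v <- rep(NA, n)
      for (w in c("original", "extended")) {
        idx <- waves == w
        if (!any(idx)) next
        c0 <- solve_logit_intercept(age[idx], p$age_slope, p$prev[[w]])
        v[idx] <- runif(sum(idx)) < plogis(c0 + p$age_slope * age[idx])
      }
      if (nm == "sex") {
        out$sex <- factor(ifelse(v, "female", "male"),
                          levels = c("female", "male"))
      } else out[[nm]] <- v
    } else if (p$type == "categorical") {
      v <- rep(NA_character_, n)
      for (w in c("original", "extended")) {
        idx <- waves == w
        if (!any(idx)) next
        v[idx] <- sample(p$levels, sum(idx), replace = TRUE,
                         prob = p$prob[[w]])
      }
      out[[nm]] <- factor(v, levels = p$levels)
    }
  }
  out$calendar_year <- exam
  s <- cohort_schema()
  keep <- s$name[!s$name %in% c("time", "event", "death", "ad_subtype")]
  out <- out[keep]
  validate_cohort(out, require_outcome = FALSE)
  out
}

# inverse-transform sample of a Gompertz event time with attained-age hazard
# h(t) = rate * exp(shape*(age + t - ref)) * exp(lp)
r_gompertz_time <- function(u, rate, shape, age, ref, lp = 0) {
  r <- rate * exp(lp + shape * (age - ref))
  if (shape == 0) return(-log(u) / r)
  t <- log1p(-log(u) * shape / r) / shape
  t
}

# per-covariate log-hazard contributions; entries named "column" apply the
# coefficient to the numeric/0-1 value, entries named "column:level" to the
# indicator of a categorical level
hazard_lp <- function(cohort, hazard) {
  lp <- rep(0, nrow(cohort))
  if (is.null(hazard$log_hr) || length(hazard$log_hr) == 0) return(lp)
  for (nm in names(hazard$log_hr)) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      x <- cohort[[parts[1]]]
      if (is.null(x)) stop("log_hr names unknown covariate: ", nm)
      x <- as.numeric(as.character(x) == parts[2])
    } else {
      x <- cohort[[nm]]
      if (is.null(x)) stop("log_hr names unknown covariate: ", nm)
      if (is.factor(x))
        stop("use 'column:level' log_hr entries for categorical covariates")
      if (is.logical(x)) x <- as.numeric(x)
    }
    lp <- lp + hazard$log_hr[[nm]] * x
  }
  lp
}

#' Generate survival outcomes for a synthetic cohort
#'
#' Dementia and dementia-free death times are drawn independently from their
#' Gompertz hazards by inverse transform on the cumulative hazard; the
#' observed time is the minimum of the two and the administrative censoring
#' time (`end_year` minus the baseline examination date). Death is recorded
#' but treated as censoring by all downstream metrics, matching the
#' cause-specific (non-competing-risk) estimand of the validation design.
#'
#' @param cohort Output of [generate_covariates()].
#' @param config A [generator_config()].
#' @return `cohort` with `time`, `event`, `death`, `ad_subtype` appended.
#' @export
generate_outcomes <- function(cohort, config) {
  validate_generator_config(config)
  n <- nrow(cohort)
  if (n == 0) {
    cohort$time <- numeric(0)
    cohort$event <- factor(character(0), levels = c("censored", "dementia"))
    cohort$death <- logical(0)
    cohort$ad_subtype <- logical(0)
    return(cohort)
  }
  dh <- config$dementia_hazard
  mh <- config$death_hazard
  t_dem <- r_gompertz_time(runif(n), dh$rate, dh$shape, cohort$age, dh$ref_age,
                           hazard_lp(cohort, dh))
  t_die <- r_gompertz_time(runif(n), mh$rate, mh$shape, cohort$age, mh$ref_age,
                           hazard_lp(cohort, mh))
  t_adm <- config$end_year - cohort$calendar_year
  time <- pmin(t_dem, t_die, t_adm)
  is_dem <- t_dem <= pmin(t_die, t_adm)
  cohort$time <- time
  cohort$event <- factor(ifelse(is_dem, "dementia", "censored"),
                         levels = c("censored", "dementia"))
  cohort$death <- !is_dem & t_die <= t_adm
  ad <- rep(NA, n)
  ad[is_dem] <- runif(sum(is_dem)) < config$p_ad_given_dementia
  cohort$ad_subtype <- ad
  validate_cohort(cohort)
  cohort
}

#' Mask covariate values missing-completely-at-random
#'
#' Applies the configured per-covariate MCAR rates; a covariate with a
#' `missing_wave` is removed for that entire wave (emulating a variable not
#' measured in one wave) and masked at `rate` in the other. Outcome fields
#' are never masked.
#'
#' @param cohort A cohort data frame.
#' @param config A [generator_config()].
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, config) {
  validate_generator_config(config)
  for (nm in names(config$missingness)) {
    ms <- config$missingness[[nm]]
    if (!nm %in% covariate_columns())
      stop("missingness configured for non-covariate column: ", nm)
    mask <- rep(FALSE, nrow(cohort))
    free <- rep(TRUE, nrow(cohort))
    if (!is.null(ms$missing_wave)) {
      inwave <- cohort$wave == ms$missing_wave
      mask[inwave] <- TRUE
      free <- !inwave
    }
    mask[free] <- runif(sum(free)) < ms$rate
    cohort[[nm]][mask] <- NA
  }
  cohort
}

#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from `config$seed` (or the `seed` argument) and runs
#' [generate_covariates()], [generate_outcomes()] and, unless disabled,
#' [inject_missingness()]. Identical configuration and seed give an
#' identical cohort.
#'
#' @param config A [generator_config()].
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @param missingness Apply the configured missingness pattern (default
#'   `TRUE`).
#' @return A cohort data frame.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL,
                            missingness = TRUE) {
  set.seed(if (is.null(seed)) config$seed else seed)
  cohort <- generate_covariates(config)
  cohort <- generate_outcomes(cohort, config)
  if (missingness) cohort <- inject_missingness(cohort, config)
  cohort
}

#' True linear predictor of the generating dementia hazard
#'
#' The log hazard ratio of each participant relative to the reference age,
#' `shape * (age - ref_age)` plus any configured per-covariate log-hazard
#' terms. Under the generator's proportional-hazards structure this is the
#' ideal predictor against which validation machinery can be checked.
#'
#' @param cohort A cohort data frame.
#' @param config A [generator_config()].
#' @return Numeric vector.
#' @export
true_linear_predictor <- function(cohort, config) {
  dh <- config$dementia_hazard
  dh$shape * (cohort$age - dh$ref_age) + hazard_lp(cohort, dh)
}

#' True cause-specific dementia risk under the generating hazard
#'
#' Closed-form `1 - exp(-H(horizon))` for the Gompertz cumulative hazard,
#' ignoring death (the net, cause-specific risk). Serves as the oracle
#' predictor for self-validation of the calibration machinery.
#'
#' @param cohort A cohort data frame (only `age` and any covariates named in
#'   `log_hr` are used).
#' @param config A [generator_config()].
#' @param horizon Prediction horizon in years (> 0).
#' @return Numeric vector of probabilities.
#' @export
true_risk <- function(cohort, config, horizon) {
  if (horizon <= 0) stop("horizon must be > 0")
  dh <- config$dementia_hazard
  r <- dh$rate * exp(hazard_lp(cohort, dh) + dh$shape * (cohort$age - dh$ref_age))
  H <- if (dh$shape == 0) r * horizon else r * expm1(dh$shape * horizon) / dh$shape
  1 - exp(-H)
}

#' Read a generator configuration from a YAML file
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [generator_config()]; keys that are absent keep their defaults, and
#' nested lists (`age_model`, `dementia_hazard`, `covariate_params`, ...)
#' are merged element-wise into the default configuration, so a file needs
#' to state only what it changes. `log_hr` entries given as a YAML map
#' become the named coefficient vector.
#'
#' @param path YAML file path.
#' @return A validated `generator_config` object.
#' @export
read_generator_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading generator configurations from YAML requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  cfg <- generator_config()
  known <- setdiff(names(cfg), "n_total")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(y)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(y[[nm]]))
      utils::modifyList(cfg[[nm]], y[[nm]]) else y[[nm]]
  }
  for (hz in c("dementia_hazard", "death_hazard"))
    if (is.list(cfg[[hz]]$log_hr)) cfg[[hz]]$log_hr <- unlist(cfg[[hz]]$log_hr)
  cfg$n_total <- cfg$n_original + cfg$n_extended
  validate_generator_config(cfg)
  cfg
}
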