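#' Run the head-to-head model validation
#'
#' Orchestrates the full external-validation analysis on a cohort (supplied
#' or generated): scoring of each model across the whole cohort (with BDSI
#' age extrapolation and DRS equation stitching) plus, for the models with
#' a restricted design age range, a design-range analysis; the full,
#' age-only and without-age predictor variants; horizon truncation and
#' Harrell's concordance per horizon; calibration and recalibration for the
#' models that publish absolute risks (DRS always; CAIDE only when a
#' score-to-probability mapping is configured); and, when the cohort has
#' missing covariates, multiple imputation with Rubin pooling of every
#' statistic.
#'
#' @param cohort A cohort data frame, or `NULL` to generate one from
#'   `config`.
#' @param config A [generator_config()] used when `cohort` is `NULL`.
#' @param models Subset of `c("caide", "bdsi", "anu_adri", "drs")`.
#' @param horizons Prediction horizons in years.
#' @param variants Subset of `c("full", "age_only", "without_age")`.
#' @param m Imputations when covariates are missing.
#' @param seed Seed for imputation and bootstrap.
#' @param n_boot Bootstrap replicates for concordance CIs (0 = point
#'   estimates only).
#' @param calibration_horizon Horizon (years) for the calibration section.
#' @param caide_risk_mapping Optional data frame (`score`, `risk`) mapping
#'   CAIDE totals to absolute probabilities; absent by default, so CAIDE
#'   appears in discrimination but not calibration output.
#' @param drs_registry DRS equation registry, see [drs_select_equation()].
#' @return An object of class `"validation_report"`: list with `results`
#'   (data frame keyed by model, variant, population, horizon), `calibration`
#'   (per-model original and recalibrated summaries), and `meta` (seed,
#'   sizes, exclusions, adaptation log).
#' @export
run_validation <- function(cohort = NULL, config = NULL,
                           models = c("caide", "bdsi", "anu_adri", "drs"),
                           horizons = c(2, 5, 10, 15),
                           variants = c("full", "age_only", "without_age"),
                           m = 5, seed = 1L, n_boot = 0,
                           calibration_horizon = 10,
                           caide_risk_mapping = NULL,
                           drs_registry = list(young = drs_equation(), old = NULL)) {
  models <- match.arg(models, several.ok = TRUE)
  variants <- match.arg(variants, several.ok = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.null(cohort)) {
    if (is.null(config)) config <- generator_config(seed = seed)
    cohort <- generate_cohort(config)
    note("cohort generated synthetically (n = %d, seed %s)",
         nrow(cohort), format(config$seed))
  }
  n_in <- nrow(cohort)
  keep <- !is.na(cohort$time) & !is.na(cohort$event) & cohort$time > 0
  cohort <- cohort[keep, , drop = FALSE]
  validate_cohort(cohort)
  n_excluded <- n_in - nrow(cohort)
  if (n_excluded > 0)
    note("%d row(s) dropped (missing outcome or non-positive follow-up)",
         n_excluded)
  if (nrow(cohort) == 0) stop("cohort empty after exclusions")

  has_missing <- any(vapply(covariate_columns(),
                            function(v) anyNA(cohort[[v]]), TRUE))
  imp <- if (has_missing) {
    note("missing covariates present: %d-fold multiple imputation (seed %s)",
         m, format(seed))
    impute_cohort(cohort, m = m, seed = seed)
  } else list(m = 1L, cohorts = list(cohort))
  note("BDSI age component extrapolated beyond the 65-79 design range at 1 point/year")
  if (is.null(drs_registry$old))
    note("no 80-95 DRS equation configured; 60-79 equation used across the full age range")
  note("DRS deprivation and ANU-ADRI social network use the 3-domain household composite")

  ev <- cohort$event == "dementia"
  horizons <- sort(horizons)

  populations <- list(all = rep(TRUE, nrow(cohort)))
  design_range <- list(bdsi = cohort$age >= 65 & cohort$age <= 79,
                       drs = cohort$age >= 60 &
                         (cohort$age < 80 | !is.null(drs_registry$old)))

  rows <- list()
  for (model in models) {
    pops <- c(list(all = populations$all),
              if (model %in% names(design_range))
                setNames(design_range[model], "design_range"))
    for (pop_name in names(pops)) {
      pop <- pops[[pop_name]]
      if (sum(pop) == 0) {
        note("%s: design-range population empty in this cohort; skipped", model)
        next
      }
      vars_here <- if (pop_name == "all") variants else "full"
      for (variant in vars_here) {
        # predictor per imputation
        preds <- lapply(imp$cohorts, function(d)
          score_variant(d[pop, , drop = FALSE], model, variant,
                        drs_registry = drs_registry))
        degenerate <- any(vapply(preds, function(p) attr(p, "degenerate"), TRUE))
        for (h in horizons) {
          rec0 <- truncate_at_horizon(
            survival_records(preds[[1]], cohort$time[pop], ev[pop]), h)
          n_events <- sum(rec0$event)
          if (degenerate || n_events == 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              model = model, variant = variant, population = pop_name,
              horizon = h, n = sum(pop), n_events = n_events,
              c = NA_real_, se = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, degenerate = TRUE,
              reason = if (n_events == 0) "no events by horizon" else
                "constant predictor in this cohort",
              stringsAsFactors = FALSE)
            next
          }
          cs <- ses <- numeric(imp$m)
          for (d in seq_len(imp$m)) {
            rec <- truncate_at_horizon(
              survival_records(preds[[d]], cohort$time[pop], ev[pop]), h)
            cr <- harrell_c(rec, n_boot = n_boot,
                            seed = if (n_boot > 0) seed + 1000L * d else NULL)
            cs[d] <- cr$c
            ses[d] <- cr$se
          }
          pooled <- pool_rubin(cs, ses)
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, variant = variant, population = pop_name,
            horizon = h, n = sum(pop), n_events = n_events,
            c = pooled$estimate, se = pooled$se,
            ci_low = if (is.na(pooled$se)) NA_real_ else
              pooled$estimate - 1.96 * pooled$se,
            ci_high = if (is.na(pooled$se)) NA_real_ else
              pooled$estimate + 1.96 * pooled$se,
            degenerate = FALSE, reason = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)

  calibration <- list()
  for (model in intersect(models, c("caide", "drs"))) {
    if (model == "caide" && is.null(caide_risk_mapping)) next
    h <- calibration_horizon
    per_imp <- lapply(imp$cohorts, function(d) {
      if (model == "drs") {
        comp <- suppressWarnings(drs_score(d, registry = drs_registry))
        risk <- pmin(pmax(comp$predicted_risk, 1e-10), 1 - 1e-10)
        lp <- comp$total
      } else {
        sc <- caide_score(d)$total
        risk <- stats::approx(caide_risk_mapping$score, caide_risk_mapping$risk,
                              xout = sc, rule = 2)$y
        risk <- pmin(pmax(risk, 1e-10), 1 - 1e-10)
        lp <- NULL
      }
      rec <- survival_records(risk, cohort$time, ev)
      orig <- calibration_intercept_slope(risk, rec, h)
      if (model == "drs") {
        rc <- recalibrate_cox(lp, rec, h)
        newr <- pmin(pmax(rc$risk, 1e-10), 1 - 1e-10)
      } else {
        rl <- recalibrate_logistic(risk, rec, h)
        newr <- rl$predictions
      }
      recal <- calibration_intercept_slope(newr, rec, h)
      list(orig = orig, recal = recal)
    })
    pool_cal <- function(get) {
      int <- pool_rubin(vapply(per_imp, function(x) get(x)$intercept, 0),
                        vapply(per_imp, function(x) get(x)$intercept_se, 0))
      slo <- pool_rubin(vapply(per_imp, function(x) get(x)$slope, 0),
                        vapply(per_imp, function(x) get(x)$slope_se, 0))
      list(intercept = int$estimate, intercept_se = int$se,
           slope = slo$estimate, slope_se = slo$se,
           bins = get(per_imp[[1]])$bins,
           n_used = get(per_imp[[1]])$n_used,
           n_excluded = get(per_imp[[1]])$n_excluded)
    }
    calibration[[model]] <- list(horizon = h,
                                 original = pool_cal(function(x) x$orig),
                                 recalibrated = pool_cal(function(x) x$recal))
  }

  out <- list(results = results, calibration = calibration,
              meta = list(seed = seed, m = imp$m, n_boot = n_boot,
                          models = models, horizons = horizons,
                          variants = variants, n = nrow(cohort),
                          n_events = sum(ev), n_excluded = n_excluded,
                          calibration_horizon = calibration_horizon,
                          log = log_lines))
  class(out) <- "validation_report"
  out
}

#' Sensitivity analyses around the main validation
#'
#' Three modes: `ad_only` restricts events to the Alzheimer's disease
#' subtype (non-AD dementia events become censoring at diagnosis);
#' `landmark_4y` drops participants with less than 4 years of
#' dementia-free follow-up (reverse-causation guard; the clock is not
#' reset); `age_strata_80` runs separate validations below and at/above
#' age 80 at baseline.
#'
#' @param cohort A cohort data frame (must carry `ad_subtype` for
#'   `ad_only`).
#' @param mode One of `"ad_only"`, `"landmark_4y"`, `"age_strata_80"`.
#' @param ... Passed to [run_validation()].
#' @return A `validation_report`, or for `age_strata_80` a named list of
#'   two (`under_80`, `over_80`).
#' @export
run_sensitivity <- function(cohort, mode = c("ad_only", "landmark_4y",
                                             "age_strata_80"), ...) {
  mode <- match.arg(mode)
  validate_cohort(cohort)
  if (mode == "ad_only") {
    is_ev <- cohort$event == "dementia"
    if (all(is.na(cohort$ad_subtype[is_ev])))
      stop("ad_only sensitivity requires ad_subtype on dementia events")
    demote <- is_ev & !cohort$ad_subtype %in% TRUE
    cohort$event[demote] <- "censored"
    cohort$ad_subtype[demote] <- NA
    rep <- run_validation(cohort, ...)
    rep$meta$sensitivity <- "ad_only"
    return(rep)
  }
  if (mode == "landmark_4y") {
    cohort <- cohort[cohort$time >= 4, , drop = FALSE]
    if (nrow(cohort) == 0) stop("empty cohort after landmark exclusion")
    rep <- run_validation(cohort, ...)
    rep$meta$sensitivity <- "landmark_4y"
    return(rep)
  }
  strata <- split(cohort, ifelse(cohort$age < 80, "under_80", "over_80"))
  if (length(strata) < 2) stop("empty age stratum")
  out <- lapply(strata[c("under_80", "over_80")], run_validation, ...)
  for (nm in names(out)) out[[nm]]$meta$sensitivity <-
    paste0("age_strata_80:", nm)
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: n = %d, %d dementia events, m = %d imputation(s)\n",
              x$meta$n, x$meta$n_events, x$meta$m))
  if (!is.null(x$meta$sensitivity))
    cat("  sensitivity mode:", x$meta$sensitivity, "\n")
  r <- x$results[x$results$population == "all", , drop = FALSE]
  fmt <- function(row) {
    if (is.na(row$c)) return("NA")
    if (!is.na(row$ci_low))
      sprintf("%.2f (%.2f-%.2f)", row$c, row$ci_low, row$ci_high)
    else sprintf("%.2f", row$c)
  }
  cat("\nC-statistics at follow-up horizons (whole cohort):\n")
  for (model in unique(r$model)) {
    cat(sprintf("  %s\n", toupper(model)))
    for (variant in unique(r$variant[r$model == model])) {
      cells <- vapply(sort(unique(r$horizon)), function(h) {
        row <- r[r$model == model & r$variant == variant & r$horizon == h, ]
        if (nrow(row) == 0) "" else fmt(row[1, ])
      }, "")
      cat(sprintf("    %-12s %s\n", variant,
                  paste(sprintf("%2gy: %s", sort(unique(r$horizon)), cells),
                        collapse = "  ")))
    }
  }
  for (model in names(x$calibration)) {
    cal <- x$calibration[[model]]
    cat(sprintf("\nCalibration (%s, %g-year horizon):\n", toupper(model),
                cal$horizon))
    cat(sprintf("  original:     intercept %.2f, slope %.2f\n",
                cal$original$intercept, cal$original$slope))
    cat(sprintf("  recalibrated: intercept %.2f, slope %.2f\n",
                cal$recalibrated$intercept, cal$recalibrated$slope))
  }
  if (length(x$meta$log) > 0) {
    cat("\nRun log:\n")
    for (l in x$meta$log) cat("  -", l, "\n")
  }
  invisible(x)
}

#' Write a validation report to files
#'
#' Emits a machine-readable long-format C-statistic table
#' (`<basename>_cstatistics.csv`), one calibration bin table per calibrated
#' model (`<basename>_calibration_<model>.csv`), and a structured JSON dump
#' of the full report (`<basename>_report.json`) that [read_report()]
#' parses back. Output is deterministic: two runs with the same seed and
#' configuration produce byte-identical files.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @param basename File name stem.
#' @return Character vector of the files written, invisibly.
#' @export
emit_report <- function(report, dir, basename = "validation") {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f_csv <- file.path(dir, paste0(basename, "_cstatistics.csv"))
  write.csv(report$results, f_csv, row.names = FALSE, na = "")
  files <- c(files, f_csv)
  for (model in names(report$calibration)) {
    f_cal <- file.path(dir, paste0(basename, "_calibration_", model, ".csv"))
    write.csv(report$calibration[[model]]$original$bins, f_cal,
              row.names = FALSE, na = "")
    files <- c(files, f_cal)
  }
  f_json <- file.path(dir, paste0(basename, "_report.json"))
  jsonlite::write_json(list(results = report$results,
                            calibration = report$calibration,
                            meta = report$meta),
                       f_json, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  files <- c(files, f_json)
  invisible(files)
}

#' Read back a JSON validation report
#'
#' @param path Path to a `_report.json` written by [emit_report()].
#' @return A `validation_report` object.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$results <- as.data.frame(x$results, stringsAsFactors = FALSE)
  for (model in names(x$calibration)) {
    for (part in c("original", "recalibrated"))
      x$calibration[[model]][[part]]$bins <-
        as.data.frame(x$calibration[[model]][[part]]$bins)
  }
  class(x) <- "validation_report"
  x
}
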