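#' Truncate follow-up at a prediction horizon
#'
#' Events after the horizon are recoded as censored at the horizon;
#' follow-up beyond the horizon is cut back to it. Works on survival-record
#' frames (logical `event`) and on cohort frames (factor `event`, where
#' `death` and `ad_subtype` are masked consistently for truncated events).
#'
#' @param x A [survival_records()] frame or a cohort data frame.
#' @param horizon Horizon in years (> 0).
#' @return `x` with `time` and `event` truncated.
#' @export
truncate_at_horizon <- function(x, horizon) {
  if (horizon <= 0) stop("horizon must be > 0")
  over <- x$time > horizon
  if (is.logical(x$event)) {
    x$event[over] <- FALSE
  } else {
    x$event[over] <- "censored"
    if ("ad_subtype" %in% names(x)) x$ad_subtype[over] <- NA
    if ("death" %in% names(x)) x$death[over] <- FALSE
  }
  x$time[over] <- horizon
  x
}

#' Kaplan-Meier event-free probability at a time point
#'
#' Product-limit estimate via [survival::survfit()]. Querying beyond the
#' last observed time returns the last estimate with attribute
#' `extrapolated = TRUE`.
#'
#' @param records A [survival_records()] frame (the predictor is ignored).
#' @param t Time in years (>= 0).
#' @return Survival probability with attribute `extrapolated`.
#' @export
km_survival <- function(records, t) {
  if (t < 0) stop("t must be >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit, times = t, extend = TRUE)$surv
  structure(s, extrapolated = t > max(records$time))
}

#' Crude incidence rate per 1000 person-years
#'
#' @param x A survival-record frame or a cohort data frame.
#' @return Events per 1000 person-years.
#' @export
incidence_rate <- function(x) {
  ev <- if (is.logical(x$event)) x$event else x$event == "dementia"
  total <- sum(x$time)
  if (nrow(x) == 0 || total <= 0) stop("no person-time")
  1000 * sum(ev) / total
}

# Binary outcome construction for calibration at a horizon: participants
# censored dementia-free before the horizon are excluded (their horizon
# status is unknown); survivors past the horizon are non-events.
calibration_outcome <- function(records, horizon) {
  r <- truncate_at_horizon(records, horizon)
  keep <- r$event | r$time >= horizon
  list(y = r$event[keep], keep = keep, n_excluded = sum(!keep))
}

#' Calibration intercept and slope of predicted risks
#'
#' Assesses agreement between predicted risks and observed event
#' frequencies by the horizon. The binary outcome is event-by-horizon;
#' participants censored dementia-free before the horizon are excluded.
#' The slope is the coefficient of `logit(predicted)` in a logistic
#' regression of the outcome (1 = ideal; < 1 = predictions too extreme);
#' the intercept (calibration-in-the-large) is the intercept of a logistic
#' fit with `logit(predicted)` as a fixed offset. The decile bin table
#' underlying a calibration plot is returned alongside, with per-bin
#' binomial confidence intervals, or Kaplan-Meier-based observed risks when
#' `observed = "km"` (censoring-robust alternative that uses all
#' participants).
#'
#' @param predicted_risk Probabilities in (0, 1).
#' @param records A [survival_records()] frame aligned with
#'   `predicted_risk` (its `predictor` column is ignored).
#' @param horizon Horizon in years.
#' @param bins Number of risk groups for the plot table (default 10).
#' @param observed `"binomial"` (default) or `"km"`.
#' @return An object of class `"calibration_result"`: `intercept`, `slope`,
#'   their standard errors, `bins` (data frame: `mean_predicted`,
#'   `observed`, `ci_low`, `ci_high`, `n`), `n_used`, `n_excluded`,
#'   `extreme` flag (slope estimated under separation-like fit warnings).
#' @export
calibration_intercept_slope <- function(predicted_risk, records, horizon,
                                        bins = 10,
                                        observed = c("binomial", "km")) {
  observed <- match.arg(observed)
  stopifnot(length(predicted_risk) == nrow(records))
  if (any(predicted_risk <= 0 | predicted_risk >= 1))
    stop("predicted risks must lie strictly inside (0, 1)")
  co <- calibration_outcome(records, horizon)
  y <- co$y
  p <- predicted_risk[co$keep]
  if (length(unique(y)) < 2)
    stop("calibration not identifiable: all observed outcomes identical")
  if (max(p) - min(p) < 1e-12)
    stop("calibration slope undefined for constant predictions")
  lp <- qlogis(p)
  extreme <- FALSE
  slope_fit <- withCallingHandlers(
    glm(y ~ lp, family = binomial()),
    warning = function(w) {
      extreme <<- TRUE
      invokeRestart("muffleWarning")
    })
  int_fit <- suppressWarnings(glm(y ~ 1 + offset(lp), family = binomial()))

  # bin table over all records (km) or the horizon-complete subset
  cuts <- unique(quantile(predicted_risk, probs = seq(0, 1, length.out = bins + 1)))
  grp_all <- cut(predicted_risk, cuts, include.lowest = TRUE)
  bin_rows <- lapply(levels(grp_all), function(g) {
    if (observed == "binomial") {
      idx <- grp_all[co$keep] == g
      nb <- sum(idx)
      if (nb == 0)
        return(data.frame(mean_predicted = NA_real_, observed = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, n = 0L))
      ev <- sum(y[idx])
      bt <- binom.test(ev, nb)
      data.frame(mean_predicted = mean(p[idx]), observed = ev / nb,
                 ci_low = bt$conf.int[1], ci_high = bt$conf.int[2], n = nb)
    } else {
      idx <- grp_all == g
      nb <- sum(idx)
      s <- km_survival(records[idx, , drop = FALSE], min(horizon, max(records$time[idx])))
      data.frame(mean_predicted = mean(predicted_risk[idx]),
                 observed = 1 - as.numeric(s),
                 ci_low = NA_real_, ci_high = NA_real_, n = nb)
    }
  })
  res <- list(intercept = unname(coef(int_fit)[1]),
              slope = unname(coef(slope_fit)[2]),
              intercept_se = sqrt(vcov(int_fit)[1, 1]),
              slope_se = sqrt(vcov(slope_fit)[2, 2]),
              bins = do.call(rbind, bin_rows),
              n_used = length(y), n_excluded = co$n_excluded,
              observed_method = observed, extreme = extreme)
  class(res) <- "calibration_result"
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: intercept = %.3f, slope = %.3f (n = %d, %d excluded before horizon)\n",
              x$intercept, x$slope, x$n_used, x$n_excluded))
  invisible(x)
}

#' Recalibrate predictions in the large (logistic intercept update)
#'
#' Finds the logit shift `delta` such that the mean of
#' `plogis(logit(p) + delta)` over horizon-complete participants equals the
#' observed event proportion by the horizon, and applies it to all
#' predictions. This is the intercept-update recalibration for models
#' published as logistic equations.
#'
#' @inheritParams calibration_intercept_slope
#' @return List with `delta`, `predictions` (shifted, same length as the
#'   input), `observed` (event proportion), `mean_original`.
#' @export
recalibrate_logistic <- function(predicted_risk, records, horizon) {
  stopifnot(length(predicted_risk) == nrow(records))
  if (any(predicted_risk <= 0 | predicted_risk >= 1))
    stop("predicted risks must lie strictly inside (0, 1)")
  co <- calibration_outcome(records, horizon)
  if (!any(co$y)) stop("no events by the horizon")
  target <- mean(co$y)
  lp <- qlogis(predicted_risk)
  f <- function(d) mean(plogis(lp[co$keep] + d)) - target
  delta <- uniroot(f, c(-30, 30), tol = .Machine$double.eps^0.75)$root
  list(delta = delta, predictions = plogis(lp + delta), observed = target,
       mean_original = mean(predicted_risk[co$keep]))
}

#' Recalibrate a Cox-type model to the validation population
#'
#' Updates the baseline survival to the validation cohort's Kaplan-Meier
#' estimate at the horizon and centers the linear predictor at the
#' validation mean: `risk_i = 1 - S(h)^exp(lp_i - mean(lp))`. Covariate
#' coefficients are untouched.
#'
#' @param linear_predictors Finite numeric vector.
#' @param records A [survival_records()] frame aligned with
#'   `linear_predictors`.
#' @param horizon Horizon in years.
#' @return List with `risk` (updated predictions), `base_survival`,
#'   `lp_mean`.
#' @export
recalibrate_cox <- function(linear_predictors, records, horizon) {
  stopifnot(all(is.finite(linear_predictors)),
            length(linear_predictors) == nrow(records))
  s <- as.numeric(km_survival(truncate_at_horizon(records, horizon), horizon))
  if (s <= 0) stop("baseline survival zero at the horizon (all events)")
  lp_mean <- mean(linear_predictors)
  list(risk = 1 - s^exp(linear_predictors - lp_mean),
       base_survival = s, lp_mean = lp_mean)
}
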