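#' Survival records
#'
#' The unit of all validation metrics: a predictor value, a follow-up time
#' in years, and an event indicator. Constructed from vectors or from a
#' cohort plus a predictor.
#'
#' @param predictor Numeric score, linear predictor or risk.
#' @param time Positive follow-up times in years.
#' @param event Logical event indicator, or the cohort `event` factor.
#' @return A data frame with columns `predictor`, `time`, `event` (logical).
#' @export
survival_records <- function(predictor, time, event) {
  if (is.factor(event) || is.character(event)) event <- event == "dementia"
  stopifnot(length(predictor) == length(time), length(time) == length(event))
  if (any(!is.finite(predictor))) stop("predictor must be finite")
  if (any(is.na(time) | time <= 0)) stop("time must be positive")
  data.frame(predictor = as.numeric(predictor), time = as.numeric(time),
             event = as.logical(event))
}

#' Harrell's concordance statistic for censored data
#'
#' Over all comparable pairs (the member with the strictly shorter
#' follow-up had the event; tied times are not comparable), the fraction in
#' which the shorter-time member has the higher predictor, crediting
#' predictor ties one half. Confidence intervals by seedable nonparametric
#' bootstrap (percentile method).
#'
#' A constant predictor is degenerate: the result carries c = 0.5 and
#' `degenerate = TRUE` rather than an error, since rank information is
#' simply absent.
#'
#' @param records A [survival_records()] data frame (>= 2 rows, >= 1
#'   event).
#' @param n_boot Bootstrap replicates for the CI (default 500; 0 skips the
#'   CI).
#' @param conf_level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `"concordance_result"`: list with `c`,
#'   `n_comparable_pairs`, `se`, `ci_low`, `ci_high`, `ci_method`,
#'   `degenerate`, `n`, `n_events`.
#' @export
harrell_c <- function(records, n_boot = 500, conf_level = 0.95, seed = NULL) {
  stopifnot(is.data.frame(records),
            all(c("predictor", "time", "event") %in% names(records)))
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records")
  if (!any(records$event)) stop("concordance undefined without events")
  degenerate <- max(records$predictor) - min(records$predictor) < 1e-12
  cnt <- .concordance_counts(records$predictor, records$time, records$event)
  if (cnt[["comparable"]] == 0)
    stop("no comparable pairs (all short follow-up times censored or tied)")
  cval <- if (degenerate) 0.5 else
    (cnt[["concordant"]] + 0.5 * cnt[["tied"]]) / cnt[["comparable"]]
  res <- list(c = cval, n_comparable_pairs = cnt[["comparable"]],
              se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              ci_method = "none", degenerate = degenerate,
              n = n, n_events = sum(records$event))
  if (n_boot > 0 && !degenerate) {
    if (!is.null(seed)) set.seed(seed)
    cb <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      k <- .concordance_counts(records$predictor[idx], records$time[idx],
                               records$event[idx])
      if (k[["comparable"]] > 0)
        cb[b] <- (k[["concordant"]] + 0.5 * k[["tied"]]) / k[["comparable"]]
    }
    cb <- cb[!is.na(cb)]
    alpha <- (1 - conf_level) / 2
    res$se <- sd(cb)
    qs <- quantile(cb, c(alpha, 1 - alpha), names = FALSE, type = 7)
    res$ci_low <- qs[1]
    res$ci_high <- qs[2]
    res$ci_method <- sprintf("bootstrap percentile (%d replicates)", n_boot)
  }
  class(res) <- "concordance_result"
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.3f", x$c))
  if (!is.na(x$ci_low))
    cat(sprintf(" (95%% CI %.3f-%.3f, %s)", x$ci_low, x$ci_high, x$ci_method))
  if (x$degenerate) cat(" [degenerate: constant predictor]")
  cat(sprintf("\n  %d records, %d events, %.0f comparable pairs\n",
              x$n, x$n_events, x$n_comparable_pairs))
  invisible(x)
}
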