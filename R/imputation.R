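#' Multiple imputation of missing covariates by chained equations
#'
#' Fills missing covariate values with `m` completed copies of the cohort
#' using fully conditional specification: each incomplete variable is
#' regressed on all other covariates plus the event indicator and the
#' Nelson-Aalen cumulative-hazard transform of follow-up time (the standard
#' way to let survival outcomes inform imputation), cycling until the
#' chains settle. Per-variable engines:
#' \itemize{
#'   \item numeric: predictive mean matching (Bayesian parameter draw,
#'     `pmm_k` nearest donors, type-1 matching), so imputations stay inside
#'     the observed support;
#'   \item logical: logistic regression with a normal approximation draw of
#'     the coefficients;
#'   \item categorical: polytomous regression ([nnet::multinom()]) drawing
#'     from the fitted class probabilities (no coefficient draw -- a mild
#'     understatement of imputation uncertainty for these variables).
#' }
#' Observed values and outcome fields are never altered; outcome fields must
#' be complete. A variable missing for an entire wave is imputed from the
#' wave in which it was observed; a variable with no observed values at all
#' is an error.
#'
#' @param cohort A cohort data frame.
#' @param m Number of completed cohorts (default 5).
#' @param seed Integer seed; identical seed gives an identical imputation
#'   set.
#' @param n_cycles Chained-equation cycles per imputation (default 10).
#' @param pmm_k Donor pool size for predictive mean matching.
#' @return An object of class `"imputation_set"`: list with `m`, `cohorts`
#'   (list of completed cohort data frames), `seed`, `methods` (named per
#'   imputed variable), `n_cycles`.
#' @export
impute_cohort <- function(cohort, m = 5, seed = 1L, n_cycles = 10, pmm_k = 5) {
  m <- as.integer(m)
  validate_cohort(cohort)
  covs <- covariate_columns()
  miss_counts <- vapply(covs, function(v) sum(is.na(cohort[[v]])), 0L)
  targets <- names(miss_counts[miss_counts > 0])
  methods <- vapply(targets, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) "pmm" else if (is.logical(x)) "logreg" else "polyreg"
  }, character(1))
  if (length(targets) == 0) {
    out <- list(m = m, cohorts = replicate(m, cohort, simplify = FALSE),
                seed = seed, methods = methods, n_cycles = n_cycles)
    class(out) <- "imputation_set"
    return(out)
  }
  fully_missing <- targets[miss_counts[targets] == nrow(cohort)]
  if (length(fully_missing) > 0)
    stop("cannot impute variable(s) with no observed values: ",
         paste(fully_missing, collapse = ", "))

  ev <- cohort$event == "dementia"
  na_hazard <- nelson_aalen(cohort$time, ev)
  # visit variables from least to most missing, ties in schema order
  targets <- targets[order(miss_counts[targets])]

  set.seed(seed)
  completed <- vector("list", m)
  for (im in seq_len(m)) {
    filled <- cohort
    for (v in targets) {
      nas <- is.na(filled[[v]])
      filled[[v]][nas] <- sample(filled[[v]][!nas], sum(nas), replace = TRUE)
    }
    for (cycle in seq_len(n_cycles)) {
      for (v in targets) {
        nas <- is.na(cohort[[v]])
        X <- impute_design(filled, ev, na_hazard, exclude = v)
        filled[[v]][nas] <- draw_imputations(
          y_obs = cohort[[v]][!nas], X_obs = X[!nas, , drop = FALSE],
          X_mis = X[nas, , drop = FALSE], method = methods[[v]], pmm_k = pmm_k)
      }
    }
    completed[[im]] <- filled
  }
  out <- list(m = m, cohorts = completed, seed = seed, methods = methods,
              n_cycles = n_cycles)
  class(out) <- "imputation_set"
  out
}

# Nelson-Aalen cumulative hazard evaluated at each subject's follow-up time
nelson_aalen <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  H <- cumsum(fit$n.event / fit$n.risk)
  stats::approx(fit$time, H, xout = time, method = "constant",
                f = 0, yleft = 0, rule = 2)$y
}

# numeric design matrix from all covariates except `exclude`, plus outcome
# summaries; rank-deficient columns are handled downstream by pivoted QR
impute_design <- function(filled, ev, na_hazard, exclude) {
  covs <- setdiff(covariate_columns(), exclude)
  cols <- lapply(covs, function(nm) {
    x <- filled[[nm]]
    if (is.logical(x)) matrix(as.numeric(x), dimnames = list(NULL, nm))
    else if (is.factor(x)) {
      mm <- model.matrix(~ x)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, seq_len(ncol(mm)))
      mm
    } else matrix(x, dimnames = list(NULL, nm))
  })
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(filled))), cols))
  cbind(X, event = as.numeric(ev), na_hazard = na_hazard)
}

draw_imputations <- function(y_obs, X_obs, X_mis, method, pmm_k) {
  # drop constant / collinear columns on the observed subset via pivoted QR
  qr0 <- qr(X_obs)
  keep <- qr0$pivot[seq_len(qr0$rank)]
  Xo <- X_obs[, keep, drop = FALSE]
  Xm <- X_mis[, keep, drop = FALSE]
  n_mis <- nrow(X_mis)
  fallback <- function() sample(y_obs, n_mis, replace = TRUE)

  if (method == "pmm") {
    qr1 <- qr(Xo)
    beta <- qr.coef(qr1, y_obs)
    res <- y_obs - drop(Xo %*% beta)
    df <- length(y_obs) - qr1$rank
    if (df < 1) return(fallback())
    sigma2 <- sum(res^2) / rchisq(1, df)
    R <- qr.R(qr1)
    beta_star <- tryCatch(
      beta + backsolve(R, rnorm(length(beta))) * sqrt(sigma2),
      error = function(e) beta)
    yhat_obs <- drop(Xo %*% beta)
    yhat_mis <- drop(Xm %*% beta_star)
    vapply(yhat_mis, function(yh) {
      d <- abs(yhat_obs - yh)
      donors <- order(d)[seq_len(min(pmm_k, length(d)))]
      y_obs[donors[sample.int(length(donors), 1)]]
    }, y_obs[1])
  } else if (method == "logreg") {
    fit <- tryCatch(
      suppressWarnings(glm.fit(Xo, as.numeric(y_obs), family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(fallback())
    beta <- coef(fit)
    vc <- tryCatch(chol2inv(chol(crossprod(Xo * sqrt(fit$weights)))),
                   error = function(e) NULL)
    beta_star <- if (is.null(vc)) beta else
      beta + drop(t(chol(vc)) %*% rnorm(length(beta)))
    p <- plogis(drop(Xm %*% beta_star))
    runif(n_mis) < p
  } else { # polyreg
    dat <- data.frame(y = factor(y_obs), Xo[, -1, drop = FALSE],
                      check.names = TRUE)
    fit <- tryCatch(
      nnet::multinom(y ~ ., data = dat, trace = FALSE, maxit = 200,
                     MaxNWts = 5000),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback())
    nd <- data.frame(Xm[, -1, drop = FALSE], check.names = TRUE)
    names(nd) <- names(dat)[-1]
    pr <- predict(fit, newdata = nd, type = "probs")
    levs <- fit$lev
    if (is.null(dim(pr))) {
      # vector return: either one row (all class probs) or two-level fits
      pr <- if (length(levs) == 2) cbind(1 - pr, pr) else matrix(pr, nrow = 1)
    }
    idx <- apply(pr, 1, function(p) sample.int(length(levs), 1, prob = p))
    out <- factor(levs[idx], levels = levels(y_obs))
    out
  }
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d completed cohorts (seed %s, %d cycles)\n",
              x$m, format(x$seed), x$n_cycles))
  if (length(x$methods) > 0) {
    cat("  imputed variables:\n")
    for (v in names(x$methods))
      cat(sprintf("    %-32s %s\n", v, x$methods[[v]]))
  } else cat("  no missing covariates; copies of the input\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-imputation estimates; total
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance.
#'
#' @param estimates Numeric vector of per-imputation estimates (length 2 or
#'   more; a single estimate is returned as-is with its own variance).
#' @param ses Numeric vector of per-imputation standard errors (same
#'   length; may be `NA` when no within variance is available).
#' @return List with `estimate`, `se`, `within`, `between`, `total_var`,
#'   `m`.
#' @examples
#' pool_rubin(c(0, 1), c(0, 0))$total_var  # (1 + 1/2) * 0.5 = 0.75
#' @export
pool_rubin <- function(estimates, ses) {
  if (length(estimates) != length(ses)) stop("length mismatch")
  m <- length(estimates)
  est <- mean(estimates)
  if (m == 1)
    return(list(estimate = est, se = ses[1], within = ses[1]^2, between = 0,
                total_var = ses[1]^2, m = 1L))
  within <- mean(ses^2)
  between <- var(estimates)
  total <- within + (1 + 1 / m) * between
  list(estimate = est, se = sqrt(total), within = within, between = between,
       total_var = total, m = m)
}
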