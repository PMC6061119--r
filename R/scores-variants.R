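#' Score a cohort with one model and variant
#'
#' Dispatches to the model's scorer and returns the predictor for the
#' requested variant: `full` is the total score (linear predictor for DRS),
#' `age_only` the age component, `without_age` the remainder, so that
#' `age_only + without_age = full` for every model and participant.
#'
#' When the resulting predictor is constant across the cohort (e.g. the
#' CAIDE age component in a cohort aged entirely over 53) the result carries
#' attribute `degenerate = TRUE`: such a predictor cannot discriminate.
#'
#' @param cohort A cohort data frame with complete covariates.
#' @param model `"caide"`, `"bdsi"`, `"anu_adri"` or `"drs"`.
#' @param variant `"full"`, `"age_only"` or `"without_age"`.
#' @param bdsi_extrapolate_age Passed to [bdsi_score()] (default `TRUE`:
#'   whole-cohort comparison mode).
#' @param drs_registry Passed to [drs_score()].
#' @param ... Further arguments to the model's scorer.
#' @return Numeric predictor vector with attributes `degenerate` (logical)
#'   and `components` (the full `score_components` frame).
#' @export
score_variant <- function(cohort,
                          model = c("caide", "bdsi", "anu_adri", "drs"),
                          variant = c("full", "age_only", "without_age"),
                          bdsi_extrapolate_age = TRUE,
                          drs_registry = list(young = drs_equation(), old = NULL),
                          ...) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  comp <- switch(model,
    caide = caide_score(cohort, ...),
    bdsi = bdsi_score(cohort, extrapolate_age = bdsi_extrapolate_age, ...),
    anu_adri = anu_adri_score(cohort, ...),
    drs = suppressWarnings(drs_score(cohort, registry = drs_registry, ...)))
  x <- switch(variant, full = comp$total, age_only = comp$age_points,
              without_age = comp$non_age_points)
  attr(x, "degenerate") <- length(x) > 1 && max(x) - min(x) < 1e-12
  attr(x, "components") <- comp
  x
}
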