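#' Outcome-classification report for a cohort
#'
#' Runs one of the outcome models end to end on a cohort table: logistic
#' fit, ROC/AUC of the fitted probabilities, the fixed-sensitivity operating
#' point, and (optionally) leave-one-out cross-validated probabilities with
#' their own ROC and the Pearson agreement between full-fit and
#' cross-validated probabilities.
#'
#' @param cohort validated cohort table.
#' @param model `"full"`, `"no-mi"` or `"no-soz"`.
#' @param loo also run leave-one-out cross-validation (default `TRUE`).
#' @param targetSensitivity sensitivity at which specificity is reported
#'   (default 0.86).
#' @return List with elements `model`, `fit` (coefficient table), `r2`,
#'   `model_p`, `auc`, `auc_p`, `operating_point`, `probabilities`, and when
#'   `loo` is set `loo_auc`, `loo_operating_point`, `loo_probabilities`,
#'   `agreement` (Pearson r and p).
#' @export
outcomeReport <- function(cohort, model = c("full", "no-mi", "no-soz"),
                          loo = TRUE, targetSensitivity = 0.86) {
  model <- match.arg(model)
  cohort <- validateCohortTable(cohort)
  fit <- fitOutcomeModel(cohort, model)
  roc <- rocAuc(fit$fitted_probabilities, cohort$outcome)
  op <- specificityAtSensitivity(roc, targetSensitivity)
  out <- list(
    model = model,
    fit = data.frame(term = names(fit$coefficients),
                     odds_ratio = unname(fit$odds_ratios),
                     ci_lower = unname(fit$ci95[, 1L]),
                     ci_upper = unname(fit$ci95[, 2L]),
                     p = unname(fit$p)),
    r2 = fit$r2_nagelkerke, model_p = fit$model_p,
    auc = roc$auc, auc_p = roc$auc_p,
    operating_point = op,
    probabilities = fit$fitted_probabilities)
  if (loo) {
    lp <- leaveOneOutProbs(cohort, model)
    ok <- !is.na(lp)
    lroc <- rocAuc(lp[ok], cohort$outcome[ok])
    out$loo_auc <- lroc$auc
    out$loo_auc_p <- lroc$auc_p
    out$loo_operating_point <- specificityAtSensitivity(lroc,
                                                        targetSensitivity)
    out$loo_probabilities <- lp
    out$agreement <- pearsonCorrelation(fit$fitted_probabilities[ok], lp[ok])
  }
  out
}

#' Write an outcome report as JSON
#'
#' @param report list from [outcomeReport()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeOutcomeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
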