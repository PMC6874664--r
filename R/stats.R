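#' Wilcoxon signed-rank test on paired values
#'
#' Paired test used to ask whether, across patients, the SOZ median MI
#' z-score exceeds the non-SOZ median. Zero differences are dropped;
#' absolute differences are ranked with midranks for ties. For n <= 25 pairs
#' the two-sided p-value comes from exact enumeration of all sign
#' assignments (computed by dynamic programming over the rank-sum
#' distribution, which is identical to full enumeration); for larger n, from
#' the normal approximation with tie-corrected variance. The signed
#' z-statistic (positive when `a` tends to exceed `b`) is always reported.
#'
#' @param a,b paired numeric vectors (or `b = NULL` and `a` a 2-column
#'   matrix of pairs).
#' @return List with `statistic` (rank sum W+ of positive differences),
#'   `z`, `p.value`, `n` (non-zero pairs) and `exact`.
#' @examples
#' wilcoxonSignedRank(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))$p.value  # 2/64
#' @export
wilcoxonSignedRank <- function(a, b = NULL) {
  if (is.null(b)) { stopifnot(ncol(a) == 2L); b <- a[, 2L]; a <- a[, 1L] }
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  if (!length(a)) stopf("no pairs supplied")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stopf("all paired differences are zero; the signed-rank test is undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sig2)
  if (n <= 25L) {
    ## exact null distribution of 2*W over all 2^n sign assignments
    w2 <- round(2 * r)
    f <- c(1)                     # f[s+1] = #assignments with doubled sum s
    for (wi in w2) f <- c(f, numeric(wi)) + c(numeric(wi), f)
    tot <- sum(f)
    s <- round(2 * W)
    pLe <- sum(f[seq_len(s + 1L)]) / tot
    pGe <- sum(f[(s + 1L):length(f)]) / tot
    p <- min(1, 2 * min(pLe, pGe))
    list(statistic = W, z = z, p.value = p, n = n, exact = TRUE)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    list(statistic = W, z = z, p.value = p, n = n, exact = FALSE)
  }
}

#' Multivariate logistic regression with the reporting used for outcome
#' models
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()], tight convergence, at most 100 iterations) with the
#' quantities conventionally reported for seizure-outcome models: odds
#' ratios with 95% Wald confidence intervals and p-values per predictor,
#' Nagelkerke (and Cox-Snell) pseudo-R-squared, the likelihood-ratio model
#' p-value against the intercept-only model, and per-patient fitted
#' probabilities. Quasi-separation (|beta| > 15 on a standardised predictor)
#' is flagged with a warning rather than reported as a finite effect.
#'
#' @param X data.frame or matrix of predictors (patients x predictors).
#' @param y binary outcome vector (1 = success).
#' @return Object of class `"logisticFit"`: a list with `coefficients`,
#'   `se`, `odds_ratios`, `ci95` (2-column matrix), `p` (Wald),
#'   `r2_nagelkerke`, `r2_coxsnell`, `model_p`, `fitted_probabilities`,
#'   `separation`, `glm` (the underlying fit).
#' @export
fitLogistic <- function(X, y) {
  X <- as.data.frame(X)
  if (!nrow(X)) stopf("empty predictor matrix")
  if (nrow(X) != length(y)) stopf("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stopf("missing cells are not allowed")
  y <- asFlag(y, "y")
  if (length(unique(y)) < 2L)
    stopf("need at least one event and one non-event")
  Xm <- as.matrix(X)                    # zero columns = intercept-only model
  if (ncol(Xm) && qr(cbind(1, Xm))$rank < ncol(Xm) + 1L)
    stopf("predictors are collinear (design matrix is rank deficient)")
  dat <- cbind(X, .y = y)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = list(epsilon = 1e-12, maxit = 100))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sds <- if (ncol(Xm)) apply(Xm, 2L, stats::sd) else numeric(0)
  sds[sds == 0] <- 1
  separation <- (ncol(Xm) > 0L && any(abs(beta[-1L] * sds) > 15)) ||
    !fit$converged
  if (separation)
    warnf("possible quasi-separation: some coefficients are diverging")
  n <- length(y)
  nullDev <- fit$null.deviance; dev <- fit$deviance
  r2cs <- 1 - exp((dev - nullDev) / n)
  r2n <- r2cs / (1 - exp(-nullDev / n))
  ci <- cbind(exp(beta - 1.96 * se), exp(beta + 1.96 * se))
  colnames(ci) <- c("lower", "upper")
  structure(list(
    coefficients = beta, se = se, odds_ratios = exp(beta), ci95 = ci,
    p = 2 * stats::pnorm(-abs(beta / se)),
    r2_nagelkerke = r2n, r2_coxsnell = r2cs,
    model_p = if (ncol(Xm)) stats::pchisq(nullDev - dev, df = ncol(Xm),
                                          lower.tail = FALSE) else NA_real_,
    fitted_probabilities = as.numeric(stats::fitted(fit)),
    separation = separation, glm = fit
  ), class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
  cat("Logistic outcome model:",
      length(x$coefficients) - 1L, "predictor(s),",
      length(x$fitted_probabilities), "patients\n")
  tab <- data.frame(OR = x$odds_ratios, lower = x$ci95[, 1L],
                    upper = x$ci95[, 2L], p = x$p)
  print(round(tab[-1L, ], 4))
  cat(sprintf("Nagelkerke R2 = %.3f; model p = %.3g%s\n", x$r2_nagelkerke,
              x$model_p, if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Fit one of the three outcome models on a cohort table
#'
#' @param cohort validated cohort table (see [readCohortTable()]).
#' @param model `"full"`, `"no-mi"` or `"no-soz"` (see [modelPredictors()]).
#' @return A `"logisticFit"` (see [fitLogistic()]).
#' @export
fitOutcomeModel <- function(cohort, model = c("full", "no-mi", "no-soz")) {
  model <- match.arg(model)
  preds <- modelPredictors(model)
  fitLogistic(cohort[preds], cohort$outcome)
}

#' ROC curve and AUC
#'
#' Classifier scores are thresholded at every observed cut-point
#' ("positive" when score >= threshold); the area under the curve is
#' computed as the normalised Mann-Whitney U statistic with half credit for
#' tied scores, and its p-value against AUC = 0.5 from the tie-corrected
#' normal approximation of U.
#'
#' @param scores numeric classifier scores (higher = more likely positive).
#' @param labels binary labels.
#' @return Object of class `"rocResult"`: `thresholds`, `sensitivity`,
#'   `specificity` (per threshold), `auc`, `auc_p`, `n_pos`, `n_neg`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- asFlag(labels, "labels")
  if (length(scores) != length(labels))
    stopf("'scores' and 'labels' must have equal length")
  if (anyNA(scores)) stopf("'scores' must not contain NA")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("both classes must be present to compute a ROC curve")
  r <- rank(scores)
  U <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  sig2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  aucP <- if (sig2 > 0) 2 * stats::pnorm(-abs((U - n1 * n0 / 2) / sqrt(sig2)))
          else 1
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / n0,
                 numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_p = aucP, n_pos = n1, n_neg = n0),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (p = %.3g), %d positive / %d negative\n",
              x$auc, x$auc_p, x$n_pos, x$n_neg))
  invisible(x)
}

#' Specificity at a fixed sensitivity
#'
#' Among operating points reaching at least the target sensitivity, returns
#' the one with maximum specificity (the achieved sensitivity is reported
#' alongside). If no threshold reaches the target, the most sensitive
#' point's specificity is returned with a warning.
#'
#' @param roc a `"rocResult"` from [rocAuc()].
#' @param targetSensitivity target in (0, 1].
#' @return List with `specificity`, `sensitivity` (achieved) and
#'   `threshold`.
#' @export
specificityAtSensitivity <- function(roc, targetSensitivity) {
  stopifnot(inherits(roc, "rocResult"))
  if (targetSensitivity <= 0 || targetSensitivity > 1)
    stopf("'targetSensitivity' must lie in (0, 1]")
  ok <- roc$sensitivity >= targetSensitivity - 1e-12
  if (!any(ok)) {
    warnf("no threshold reaches sensitivity %.3g; reporting the most sensitive point",
          targetSensitivity)
    ok <- roc$sensitivity == max(roc$sensitivity)
  }
  i <- which(ok)[which.max(roc$specificity[ok])]
  list(specificity = roc$specificity[i], sensitivity = roc$sensitivity[i],
       threshold = roc$thresholds[i])
}

#' Leave-one-out cross-validated outcome probabilities
#'
#' For each patient, refits the logistic model on the remaining patients and
#' predicts that patient's probability of surgical success. Folds that fail
#' to fit yield `NA` with a message.
#'
#' @param cohort validated cohort table.
#' @param model predictor subset, as in [modelPredictors()].
#' @return Numeric vector of probabilities in cohort order.
#' @export
leaveOneOutProbs <- function(cohort, model = c("full", "no-mi", "no-soz")) {
  model <- match.arg(model)
  preds <- modelPredictors(model)
  X <- cbind(1, as.matrix(cohort[preds]))
  y <- asFlag(cohort$outcome, "outcome")
  n <- nrow(X)
  if (n < length(preds) + 2L)
    stopf("cohort too small (%d) for %d predictors", n, length(preds))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X[-i, , drop = FALSE], y[-i],
                                      family = stats::binomial(),
                                      control = list(epsilon = 1e-10,
                                                     maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("leave-one-out fold ", i, " not estimable; probability set NA")
      next
    }
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0          # aliased (constant) columns drop out
    out[i] <- stats::plogis(sum(X[i, ] * cf))
  }
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param a,b numeric vectors of equal length (>= 3) with non-zero variance.
#' @return List with `r` and `p.value` (two-sided, t with n-2 df).
#' @export
pearsonCorrelation <- function(a, b) {
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  if (length(a) < 3L) stopf("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("zero variance in one of the inputs")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}

#' Sensitivity of outcome classification to the atlas neighbourhood size
#'
#' Rebuilds the normative atlas for each neighbourhood size k, recomputes MI
#' z-scores and per-patient subtraction scores, refits the full outcome
#' model and reports the resulting AUC — asking whether the choice of k
#' materially changes outcome classification.
#'
#' @param electrodes electrode table with `mi` and clinical flags for the
#'   whole cohort (must carry `patient_id`).
#' @param cohort cohort table with `patient_id` and all predictors; its
#'   `subtraction_mi_z` column is replaced per k.
#' @param mesh a [SurfaceMesh-class].
#' @param ks neighbourhood sizes to try (default 10, 20, 30, 40, 50, 60).
#' @param model which outcome model to refit (default `"full"`).
#' @return data.frame with one row per k: `k`, `auc`.
#' @export
kSensitivityAnalysis <- function(electrodes, cohort, mesh,
                                 ks = c(10, 20, 30, 40, 50, 60),
                                 model = "full") {
  electrodes <- validateElectrodeTable(electrodes)
  if (!("patient_id" %in% names(cohort)))
    stopf("'cohort' must carry a patient_id column to merge scores")
  pool <- electrodes[isNonEpileptic(electrodes) & !is.na(electrodes$mi), ,
                     drop = FALSE]
  if (nrow(pool) < max(ks))
    stopf("non-epileptic pool (%d) smaller than max k (%d)",
          nrow(pool), max(ks))
  aucs <- vapply(ks, function(k) {
    atlas <- buildAtlas(pool, mesh, k = k)
    z <- miZscore(electrodes, atlas, mesh)
    subs <- cohortSubtractionScores(z)
    co <- cohort
    co$subtraction_mi_z <-
      subs$subtraction_mi_z[match(co$patient_id, subs$patient_id)]
    if (anyNA(co$subtraction_mi_z))
      stopf("patients without subtraction score at k = %d", k)
    fit <- fitOutcomeModel(co, model)
    rocAuc(fit$fitted_probabilities, co$outcome)$auc
  }, numeric(1))
  data.frame(k = ks, auc = aucs)
}
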