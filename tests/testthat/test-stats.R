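test_that("signed-rank exact p matches full sign enumeration", {
  # 6 all-positive differences: one-sided 1/64, two-sided 2/64
  w <- wilcoxonSignedRank(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_true(w$exact)
  expect_equal(w$p.value, 2 / 64)
  expect_equal(w$statistic, 21)

  # brute force over all 2^n sign assignments, n <= 12, with midranks
  set.seed(31)
  for (rep_ in 1:5) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), 1)            # rounding induces ties
    d <- d[d != 0]
    if (length(d) < 2) next
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    Wall <- as.numeric(signs %*% r)
    pEnum <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
    w <- wilcoxonSignedRank(d, numeric(length(d)))
    expect_equal(w$p.value, pEnum, tolerance = 1e-12)
  }
})

test_that("signed-rank z and large-n p agree with the reference implementation", {
  set.seed(32)
  a <- rnorm(40); b <- rnorm(40, 0.3)
  w <- wilcoxonSignedRank(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_false(w$exact)
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-6)
  expect_equal(unname(w$statistic), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(abs(w$z), qnorm(ref$p.value / 2, lower.tail = FALSE),
               tolerance = 1e-6)
  # sign convention: positive z when first member tends larger; antisymmetric
  expect_gt(wilcoxonSignedRank(b + 1, b)$z, 0)
  expect_equal(wilcoxonSignedRank(b, a)$z, -w$z, tolerance = 1e-12)

  expect_error(wilcoxonSignedRank(c(1, 2), c(1, 2)), "undefined")
})

test_that("logistic OR on a 2x2 table equals the cross-product ratio", {
  y <- c(rep(1, 20), rep(0, 10), rep(1, 5), rep(0, 15))
  x <- c(rep(1, 30), rep(0, 20))
  fit <- fitLogistic(data.frame(exposure = x), y)
  expect_equal(unname(fit$odds_ratios["exposure"]), 6.0, tolerance = 1e-6)
  # score equations hold at convergence
  X <- cbind(1, x)
  g <- t(X) %*% (y - fit$fitted_probabilities)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("intercept-only fitted probability equals prevalence and R2 is zero", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fitLogistic(data.frame(row.names = seq_along(y)), y)
  expect_equal(fit$fitted_probabilities, rep(0.30, 100), tolerance = 1e-9)
  expect_equal(fit$r2_nagelkerke, 0, tolerance = 1e-9)
  # a constant predictor is collinear with the intercept
  expect_error(fitLogistic(data.frame(const = rep(1, 100)), y), "collinear")
})

test_that("logistic guards: collinearity, missing cells, separation", {
  set.seed(34)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  X$c <- X$a + 2 * X$b
  y <- rbinom(40, 1, 0.5)
  expect_error(fitLogistic(X, y), "collinear")
  X2 <- data.frame(a = rnorm(40)); X2$a[3] <- NA
  expect_error(fitLogistic(X2, y), "missing")
  sep <- data.frame(a = c(rnorm(20, -3), rnorm(20, 3)))
  ysep <- rep(0:1, each = 20)
  expect_warning(fit <- fitLogistic(sep, ysep), "separation")
  expect_true(fit$separation)
  expect_gt(fit$r2_nagelkerke, 0.95)
})

test_that("logistic recovers generating coefficients on synthetic cohorts", {
  set.seed(35)
  hits <- 0; total <- 0
  for (s in 1:20) {
    sim <- simulateCohort(cohortParams(nPatients = 123, seed = 400 + s),
                          sphereMesh(10, 14))
    fit <- suppressWarnings(fitOutcomeModel(sim$cohort, "full"))
    beta <- sim$truth$beta
    est <- fit$coefficients[names(beta)]
    se <- fit$se[names(beta)]
    hits <- hits + sum(abs(est - beta) <= 2 * se)
    total <- total + length(beta)
  }
  expect_gte(hits / total, 10 / 11)
})

test_that("AUC equals the exhaustive pairwise Mann-Whitney oracle", {
  set.seed(36)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    roc <- rocAuc(scores, labels)
    expect_equal(roc$auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, tie behaviour and monotonicity are correct", {
  roc <- rocAuc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1.0)
  tied <- rocAuc(rep(5, 10), rep(0:1, 5))
  expect_equal(tied$auc, 0.5)
  set.seed(37)
  r <- rocAuc(rnorm(50), rbinom(50, 1, 0.4))
  expect_true(all(diff(r$sensitivity) <= 1e-12))
  expect_true(all(diff(r$specificity) >= -1e-12))
  expect_error(rocAuc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(38)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  ours <- rocAuc(scores, labels)$auc
  ref <- as.numeric(suppressMessages(
    pROC::auc(labels, scores, direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("specificity at fixed sensitivity follows the max-specificity rule", {
  perfect <- rocAuc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  op <- specificityAtSensitivity(perfect, 0.86)
  expect_equal(op$specificity, 1.0)
  expect_gte(op$sensitivity, 0.86)

  tied <- rocAuc(rep(5, 10), rep(0:1, 5))
  expect_equal(specificityAtSensitivity(tied, 0.86)$specificity, 0.0)

  set.seed(39)
  scores <- rnorm(20); labels <- rbinom(20, 1, 0.5)
  roc <- rocAuc(scores, labels)
  op <- specificityAtSensitivity(roc, 0.6)
  # brute force over every cut-point
  best <- -1; sensAt <- NA
  for (t in c(sort(unique(scores)), Inf)) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens >= 0.6 && spec > best) { best <- spec; sensAt <- sens }
  }
  expect_equal(op$specificity, best)
  expect_equal(op$sensitivity, sensAt)
})

test_that("leave-one-out probabilities equal an independent refit oracle", {
  set.seed(40)
  sim <- simulateCohort(cohortParams(nPatients = 40,
                                     electrodesPerPatient = 20, seed = 41),
                        sphereMesh(8, 10))
  co <- sim$cohort
  probs <- leaveOneOutProbs(co, "no-soz")
  preds <- modelPredictors("no-soz")
  for (i in sample(nrow(co), 5)) {
    dat <- co[-i, c(preds, "outcome")]
    fit <- suppressWarnings(glm(outcome ~ ., data = dat, family = binomial,
                                control = list(epsilon = 1e-10,
                                               maxit = 100)))
    oracle <- unname(predict(fit, co[i, preds], type = "response"))
    expect_equal(probs[i], oracle, tolerance = 1e-8)
  }
})

test_that("identical patients get identical leave-one-out probabilities", {
  one <- simulateCohort(cohortParams(nPatients = 20,
                                     electrodesPerPatient = 20, seed = 42),
                        sphereMesh(8, 10))$cohort[1, ]
  co <- one[rep(1, 20), ]
  co$outcome <- rep(c(0L, 1L), 10)    # same covariates, mixed outcomes
  probs <- suppressMessages(leaveOneOutProbs(co, "full"))
  expect_lt(diff(range(probs[co$outcome == 0])), 1e-8)
  expect_lt(diff(range(probs[co$outcome == 1])), 1e-8)
})

test_that("pearson correlation matches the covariance formula", {
  a <- 1:10
  expect_equal(pearsonCorrelation(a, 2 * a + 1)$r, 1.0)
  expect_equal(pearsonCorrelation(a, -a)$r, -1.0)
  set.seed(43)
  x <- rnorm(50); y <- rnorm(50)
  r <- pearsonCorrelation(x, y)
  expect_equal(r$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  tstat <- r$r * sqrt(48 / (1 - r$r^2))
  expect_equal(r$p.value, 2 * pt(-abs(tstat), 48), tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "variance")
})

test_that("k-sweep is deterministic and saturates at the pool size", {
  mesh <- sphereMesh(10, 14)
  sim <- simulateCohort(cohortParams(nPatients = 40,
                                     electrodesPerPatient = 40, seed = 44),
                        mesh)
  pool <- sim$electrodes[isNonEpileptic(sim$electrodes), ]
  t1 <- suppressWarnings(kSensitivityAnalysis(sim$electrodes, sim$cohort, mesh,
                             ks = c(10, 20)))
  t2 <- suppressWarnings(kSensitivityAnalysis(sim$electrodes, sim$cohort, mesh,
                             ks = c(10, 20)))
  expect_identical(t1, t2)

  # k = pool size reduces to the global-standardisation pipeline
  kAll <- nrow(pool)
  t3 <- suppressWarnings(
    kSensitivityAnalysis(sim$electrodes, sim$cohort, mesh, ks = kAll))
  z <- miZscore(sim$electrodes, mesh = mesh, pool = pool, k = kAll)
  expect_equal(z$z, (z$mi - mean(pool$mi)) / sd(pool$mi), tolerance = 1e-12)
  subs <- cohortSubtractionScores(z)
  co <- sim$cohort
  co$subtraction_mi_z <- subs$subtraction_mi_z[match(co$patient_id,
                                                     subs$patient_id)]
  fit <- suppressWarnings(fitOutcomeModel(co, "full"))
  expect_equal(t3$auc, rocAuc(fit$fitted_probabilities, co$outcome)$auc,
               tolerance = 1e-12)
})
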