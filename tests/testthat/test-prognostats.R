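test_that("ROC handles perfect separation, chance, and tie-only scores", {
  r <- roc_analysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), ci = "none")
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$direction, "higher")

  # 2 of 4 positive-negative pairs won
  r2 <- roc_analysis(c(3, 1, 2, 4), c(FALSE, TRUE, FALSE, TRUE), ci = "none")
  expect_equal(r2$auc, 0.5)

  expect_warning(r3 <- roc_analysis(rep(2, 6), rep(c(TRUE, FALSE), 3),
                                    ci = "none"), "degenerate")
  expect_equal(r3$auc, 0.5)
  expect_true(r3$degenerate)
  expect_true(is.na(r3$cutoff))

  expect_error(roc_analysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals the exhaustive pairwise win fraction on random instances", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(0:1, 1))   # ties likely when rounded
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- suppressWarnings(roc_analysis(scores, labels, direction = "higher",
                                       ci = "none"))
    expect_equal(r$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC and the Youden operating point are invariant to monotone transforms", {
  set.seed(21)
  scores <- rnorm(40, mean = 2)
  labels <- scores + rnorm(40) > 2
  base <- roc_analysis(scores, labels, ci = "none")
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 5 * x - 7)) {
    tr <- roc_analysis(f(scores), labels, ci = "none")
    expect_equal(tr$auc, base$auc)
    expect_equal(tr$sensitivity, base$sensitivity)
    expect_equal(tr$specificity, base$specificity)
  }
})

test_that("auto orientation flips low-is-positive scores and reports the rule", {
  set.seed(3)
  mhri_like <- c(rnorm(40, 1.4, 0.15), rnorm(5, 2.2, 0.4))
  closed <- rep(c(TRUE, FALSE), c(40, 5))
  r <- roc_analysis(mhri_like, closed, ci = "none")
  expect_gte(r$auc, 0.5)
  expect_equal(r$direction, "lower")
  expect_match(r$rule, "<")
  # the reported J always equals sens + spec - 1 at the reported cutoff
  pred_pos <- mhri_like < r$cutoff
  expect_equal(mean(pred_pos[closed]), r$sensitivity)
  expect_equal(mean(!pred_pos[!closed]), r$specificity)
  expect_equal(r$youden_j, r$sensitivity + r$specificity - 1)
})

test_that("bootstrap and DeLong intervals bracket the point AUC", {
  set.seed(8)
  scores <- c(rnorm(30), rnorm(30, 1.2))
  labels <- rep(c(FALSE, TRUE), each = 30)
  set.seed(99)   # seeds the stratified bootstrap
  rb <- roc_analysis(scores, labels, ci = "bootstrap", boot_n = 500)
  expect_true(rb$auc_ci_low <= rb$auc && rb$auc <= rb$auc_ci_high)
  rd <- roc_analysis(scores, labels, ci = "delong")
  expect_true(rd$auc_ci_low <= rd$auc && rd$auc <= rd$auc_ci_high)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(rd$auc, as.numeric(pROC::auc(pr)))
  pci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(rd$auc_ci_low, rd$auc_ci_high), pci[c(1, 3)],
               tolerance = 1e-8)
})

test_that("Youden's J is sensitivity plus specificity minus one", {
  expect_equal(youden_from_rates(0.91, 1.00), 0.91)
  expect_equal(youden_from_rates(1, 1), 1)
  expect_equal(youden_from_rates(0.923, 0.789), 0.712)
  expect_equal(round(youden_from_rates(0.923, 0.789), 2), 0.71)
  expect_error(youden_from_rates(1.2, 0.5), "sensitivity")
})

test_that("Bland-Altman bias and limits follow the sample-SD formula", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  # differences 1, -1, 1, -1: sample SD = 2/sqrt(3)
  ba <- bland_altman(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2.263, tolerance = 1e-3)
  # constant offset: bias shifts, width collapses
  bc <- bland_altman(c(1, 2, 3) + 0.1, c(1, 2, 3))
  expect_equal(bc$bias, 0.1)
  expect_equal(bc$loa_high - bc$loa_low, 0)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("ICC matches an independent two-way ANOVA reference and its variants", {
  # 6 x 4 rating matrix; reference values computed independently with a
  # variance-components implementation (pingouin.intraclass_corr)
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  expect_equal(icc(m, "ICC2_1")$icc_value, 0.289764, tolerance = 1e-6)
  expect_equal(icc(m, "ICC3_1")$icc_value, 0.714841, tolerance = 1e-6)
  expect_equal(icc(m, "ICC1_1")$icc_value, 0.165742, tolerance = 1e-5)
  expect_match(icc(m)$icc_model_label, "absolute agreement")
  expect_error(icc(m[1:2, ]), "3 subjects")
  expect_error(icc(m[, 1, drop = FALSE]), "2 raters")
})

test_that("ICC rises to one as rater noise vanishes and is null for pure noise", {
  set.seed(5)
  subj <- rnorm(60, sd = 1)
  iccs <- vapply(c(1, 0.5, 0.1, 0.01), function(s) {
    icc(cbind(subj + rnorm(60, sd = s), subj + rnorm(60, sd = s)))$icc_value
  }, numeric(1))
  expect_true(all(diff(iccs) > 0))
  expect_gt(iccs[4], 0.999)
  expect_equal(icc(cbind(subj, subj))$icc_value, 1)
  set.seed(6)
  noise <- icc(cbind(rnorm(500), rnorm(500)))$icc_value
  expect_lt(abs(noise), 0.1)
})

test_that("Spearman correlation matches the rank-difference formula", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)   # monotone decreasing
  set.seed(14)
  x <- rnorm(15); y <- rnorm(15)       # continuous: no ties
  expect_equal(spearman(x, y)$rho, oracle_spearman_rho(x, y),
               tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("group tests dispatch by normality, exactness and variable type", {
  set.seed(20)
  df <- data.frame(
    g = rep(c("a", "b"), each = 25),
    normal = c(rnorm(25, 0), rnorm(25, 1)),
    skewed = rexp(50) + rep(c(0, 2), each = 25),
    cat = factor(rep(c("x", "y"), 25))
  )
  res <- group_tests(df, "g", c("normal", "skewed", "cat"))
  expect_equal(res$test[res$variable == "normal"], "t-test")
  expect_match(res$test[res$variable == "skewed"], "Mann-Whitney")
  expect_equal(res$test[res$variable == "cat"], "Fisher exact")
  expect_true(all(res$p_value[1:2] < 0.01))

  # identical groups carry no signal
  df2 <- data.frame(g = rep(c("a", "b"), each = 6), v = rep(rexp(6), 2))
  res2 <- group_tests(df2, "g", "v")
  expect_gte(res2$p_value, 0.99)
  expect_error(group_tests(df[df$g == "a", ], "g", "normal"), "two levels")
})

test_that("the exact small-sample Mann-Whitney p matches enumeration", {
  # complete separation at 3 vs 45: the two-sided exact p is 2 / C(48, 3);
  # the controls are strongly right-skewed so the dispatcher takes the rank
  # test, and the tiny case group makes the exact path applicable
  y <- (seq_len(45))^3
  x <- max(y) + c(1, 2, 3)       # all larger than every control
  res <- octmhri:::compare_continuous(x, y)
  expect_match(res$test, "exact")
  expect_equal(res$p_value, 2 / choose(48, 3), tolerance = 1e-12)
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  set.seed(33)
  tabs <- c(list(matrix(c(2, 1, 27, 18), 2, byrow = TRUE)),
            replicate(30, matrix(rpois(4, 8), 2), simplify = FALSE))
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("outcome labels respect the inclusive 0.3 logMAR boundary", {
  df <- data.frame(closure = c("success", "success", "failure"),
                   post_va_logmar = c(0.3, 0.4, 0.1))
  out <- classify_outcomes(df)
  expect_identical(out$visual_success, c(TRUE, FALSE, NA))
  expect_identical(out$closure_success, c(TRUE, TRUE, FALSE))
})

test_that("the acuity regression reports coefficients, CIs and VIF diagnostics", {
  cfg <- cohort_config(n_eyes = 600, va_intercept = 0.5, seed = 55)
  co <- generate_cohort(cfg)
  fit <- fit_postva_regression(co)
  cf <- fit$coefficients
  expect_setequal(cf$term, c("mhri", "mld_um", "age_years", "pre_va_logmar",
                             "surgery"))
  expect_true(all(cf$ci_low <= cf$estimate & cf$estimate <= cf$ci_high))
  expect_equal(cf$tolerance * cf$vif, rep(1, nrow(cf)), tolerance = 1e-12)
  expect_equal(fit$n, sum(co$closure == "success"))
  # duplicated predictor: rank deficiency is reported with the column
  co$mhri2 <- co$mhri
  expect_error(fit_postva_regression(co, predictors = c("mhri", "mhri2")),
               "rank deficient")
})

test_that("regression on orthogonal standardized predictors has unit VIF", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(2)
  df <- data.frame(post_va_logmar = 0.3 + 0.1 * x1 - 0.2 * x2 + rnorm(n, 0, 0.05),
                   a = x1, b = x2)
  fit <- fit_postva_regression(df, predictors = c("a", "b"),
                               closed_only = FALSE)
  expect_equal(fit$coefficients$vif, c(1, 1), tolerance = 1e-12)
  expect_equal(fit$coefficients$tolerance, c(1, 1), tolerance = 1e-12)
})

test_that("regression recovers known generating coefficients within 3 SE", {
  cfg <- cohort_config(n_eyes = 2000, va_intercept = 0.5,
                       beta_mhri = 0.581, beta_mld = 0.003, beta_preva = 0.2,
                       seed = 404)
  co <- generate_cohort(cfg)
  fit <- fit_postva_regression(co)
  sm <- summary(fit$fit)$coefficients
  for (p in c("mhri", "mld_um", "pre_va_logmar")) {
    truth <- switch(p, mhri = cfg$beta_mhri, mld_um = cfg$beta_mld,
                    pre_va_logmar = cfg$beta_preva)
    est <- sm[p, "Estimate"]; se <- sm[p, "Std. Error"]
    expect_lt(abs(est - truth), 3 * se)
  }
})
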