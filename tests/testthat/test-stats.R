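# Statistical toolkit: ROC/AUC, DeLong, summary-statistic tests,
# imputation, outliers, FDR, permutation prognostic AUC, annual change.

test_that("confusion metrics and balanced accuracy", {
  expect_equal(balanced_accuracy(1, 1), 1)
  expect_equal(balanced_accuracy(0.6, 0.8), 0.7)
  scores <- c(-2, -1, 1, 2); truth <- c(FALSE, FALSE, TRUE, TRUE)
  cm <- confusion_metrics(scores, truth)
  expect_equal(c(cm$sensitivity, cm$specificity, cm$bac), c(1, 1, 1))
  expect_error(confusion_metrics(scores, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(1:4, c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(1:4, c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  with_seed <- brainpattern:::with_seed
  with_seed(41, {
    for (r in 1:5) {
      n <- sample(20:200, 1)
      scores <- sample(1:20, n, replace = TRUE)  # heavy ties
      truth <- as.logical(rbinom(n, 1, 0.4))
      if (length(unique(truth)) < 2) next
      expect_equal(roc_auc(scores, truth)$auc, pairwise_auc(scores, truth))
    }
  })
})

test_that("DeLong agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  with_seed <- brainpattern:::with_seed
  with_seed(42, {
    n <- 80
    truth <- rep(c(TRUE, FALSE), each = n / 2)
    sa <- rnorm(n) + truth
    sb <- 0.5 * sa + rnorm(n)
    dl <- delong_test(sa, sb, truth, paired = TRUE)
    pr <- pROC::roc.test(pROC::roc(truth, sa, quiet = TRUE),
                         pROC::roc(truth, sb, quiet = TRUE),
                         method = "delong", paired = TRUE)
    expect_equal(dl$z, unname(pr$statistic), tolerance = 1e-10)
    expect_equal(dl$p, pr$p.value, tolerance = 1e-10)

    truth_b <- rep(c(TRUE, FALSE), each = 30)
    sc <- rnorm(60) + 0.3 * truth_b
    du <- delong_test(sa, sc, truth, truth_b, paired = FALSE)
    pu <- pROC::roc.test(pROC::roc(truth, sa, quiet = TRUE),
                         pROC::roc(truth_b, sc, quiet = TRUE),
                         method = "delong", paired = FALSE)
    expect_equal(du$z, unname(pu$statistic), tolerance = 1e-10)
    expect_equal(auc_variance(sa, truth),
                 pROC::var(pROC::roc(truth, sa, quiet = TRUE)),
                 tolerance = 1e-10)
  })
})

test_that("identical paired scores give Z = 0, p = 1", {
  truth <- rep(c(TRUE, FALSE), 10)
  s <- rnorm(20)
  dl <- delong_test(s, s, truth, paired = TRUE)
  expect_equal(dl$z, 0)
  expect_equal(dl$p, 1)
})

test_that("paired DeLong reduces to unpaired when covariances vanish", {
  with_seed <- brainpattern:::with_seed
  with_seed(43, {
    n <- 100
    truth <- rep(c(TRUE, FALSE), each = n / 2)
    sa <- rnorm(n) + truth
    sb <- rnorm(n) + 0.5 * truth   # independent of sa
    pa <- brainpattern:::delong_placements(sa, truth)
    pb <- brainpattern:::delong_placements(sb, truth)
    m <- length(pa$v10); nn <- length(pa$v01)
    cov_terms <- 2 * (cov(pa$v10, pb$v10) / m + cov(pa$v01, pb$v01) / nn)
    paired_var <- delong_test(sa, sb, truth, paired = TRUE)$var_diff
    unpaired_var <- auc_variance(sa, truth) + auc_variance(sb, truth)
    # algebraic identity: paired variance = sum of variances - covariances
    expect_equal(paired_var, unpaired_var - cov_terms, tolerance = 1e-12)
    # and on independent scores the covariance itself is negligible
    expect_lt(abs(cov_terms), 0.3 * unpaired_var)
  })
})

test_that("summary-statistic Welch t matches t.test on raw data", {
  with_seed <- brainpattern:::with_seed
  with_seed(44, {
    x <- rnorm(25, 10, 3); y <- rnorm(40, 12, 5)
    ours <- welch_t_summary(mean(x), sd(x), 25, mean(y), sd(y), 40)
    ref <- t.test(x, y)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  })
  expect_equal(welch_t_summary(5, 2, 10, 5, 3, 12)$statistic, 0)
  expect_equal(cohens_d_pooled(5, 2, 10, 5, 3, 12), 0)
})

test_that("chi-square and Fisher follow their exact definitions", {
  expect_equal(pearson_chisq(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  expect_error(pearson_chisq(rbind(c(0, 0), c(5, 5))), "empty margin")
  # oracle: exhaustive hypergeometric sum for the two-sided Fisher p
  tab <- rbind(c(1, 9), c(11, 3))
  # draw 10 (row one) from 12 + 12 (column totals); a = 1
  probs <- dhyper(0:10, 12, 12, 10)
  p_oracle <- sum(probs[probs <= dhyper(1, 12, 12, 10) * (1 + 1e-7)])
  expect_equal(fisher_exact(tab)$p, p_oracle, tolerance = 1e-10)
})

test_that("Mann-Whitney and paired t expose the expected statistics", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)   # all pairs favour y
  with_seed <- brainpattern:::with_seed
  with_seed(45, {
    x0 <- rnorm(20); x1 <- x0 + 0.5 + rnorm(20, 0, 0.3)
    pt <- paired_t(x0, x1)
    ref <- t.test(x1 - x0)
    expect_equal(pt$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pt$d, mean(x1 - x0) / sd(x1 - x0), tolerance = 1e-12)
  })
})

test_that("KNN imputation follows the documented contract", {
  df <- data.frame(a = c(1, 1, 1, 1, 1, 1), b = c(2, 2, 2, 2, 2, NA),
                   c = c(5, 6, 7, 5, 6, 7))
  out <- knn_impute(df, k = 5)
  expect_equal(out$b[6], 2)  # identical rows share the common value
  clean <- data.frame(a = rnorm(6), b = rnorm(6))
  expect_identical(knn_impute(clean, k = 3), clean)
  # excluded (outcome) columns are untouched and unused
  df2 <- df; df2$outcome <- c(1, NA, 0, 1, 0, 1)
  out2 <- knn_impute(df2, k = 5, exclude = "outcome")
  expect_identical(out2$outcome, df2$outcome)
  bad <- data.frame(a = rnorm(6), b = rep(NA_real_, 6))
  expect_error(knn_impute(bad), "all values missing")
})

test_that("outlier boundary is strict", {
  x <- c(1, 2, 3, 4, 5)
  k_exact <- 2 / sd(x)         # value 5 sits exactly at mean + k*sd
  expect_false(flag_outliers(x, k_sd = k_exact)[5])
  expect_true(flag_outliers(x, k_sd = k_exact * 0.999)[5])
  expect_equal(sum(flag_outliers(c(rnorm(100), 1e6))), 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  with_seed <- brainpattern:::with_seed
  p <- with_seed(46, runif(50))
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("permutation prognostic AUC is reproducible and bounded", {
  with_seed <- brainpattern:::with_seed
  score <- with_seed(47, rnorm(40))
  outcome <- rep(c(0, 1), 20)
  r1 <- permutation_outcome_auc(score, outcome, n_perm = 500, seed = 5)
  r2 <- permutation_outcome_auc(score, outcome, n_perm = 500, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 501)
  # perfectly predictive score attains the minimal p
  sep <- c(rnorm(20, -5), rnorm(20, 5))
  out <- rep(c(0, 1), each = 20)
  expect_equal(permutation_outcome_auc(sep, out, 500, seed = 6)$p, 1 / 501)
  expect_error(permutation_outcome_auc(score, rep(1, 40)), "both outcome")
  # doubling n_perm moves p by less than 2 binomial SEs
  pa <- permutation_outcome_auc(score, outcome, 400, seed = 7)$p
  pb <- permutation_outcome_auc(score, outcome, 800, seed = 8)$p
  expect_lt(abs(pa - pb), 2 * sqrt(0.25 / 400))
})

test_that("annual change regression is exact and rejects degenerate input", {
  dx <- c(1, 2, 3, 4, 5); yrs <- c(8, 9, 10, 9, 8)
  res <- suppressWarnings(annual_change_regression(dx, 2 * dx, yrs))
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_error(annual_change_regression(rep(1, 5), rnorm(5), 9), "constant")
  expect_error(annual_change_regression(1:2, 1:2, 9), "at least 3")
  with_seed <- brainpattern:::with_seed
  with_seed(48, {
    r0 <- annual_change_regression(rnorm(200), rnorm(200), 9)
    expect_lt(r0$r_squared, 0.05)
  })
})

test_that("mixed model detects planted interactions and reports variance", {
  with_seed <- brainpattern:::with_seed
  with_seed(49, {
    n <- 30
    df <- expand.grid(subject_id = sprintf("s%02d", 1:n), timepoint = 0:1)
    df$group <- rep(rep(c("patient", "control"), each = n / 2), 2)
    b_subj <- rnorm(n, 0, 1)[match(df$subject_id, unique(df$subject_id))]
    df$y <- b_subj + 0.8 * (df$group == "patient") * df$timepoint +
      rnorm(nrow(df), 0, 0.3)
    res <- lmm_interaction(df, "y", "group", "timepoint", "subject_id")
    expect_lt(res$p, 0.01)
    expect_gt(res$varcomp[["random_intercept"]], 0.3)
    expect_true(res$r2_conditional >= res$r2_marginal)
    expect_true(res$r2_conditional <= 1 && res$r2_marginal >= 0)
  })
})

test_that("zero between-subject variance yields a null random intercept", {
  with_seed <- brainpattern:::with_seed
  with_seed(50, {
    n <- 40
    df <- expand.grid(subject_id = sprintf("s%02d", 1:n), timepoint = 0:1)
    df$group <- rep(rep(c("patient", "control"), each = n / 2), 2)
    df$y <- rnorm(nrow(df))
    res <- lmm_interaction(df, "y", "group", "timepoint", "subject_id")
    expect_lt(res$varcomp[["random_intercept"]], 0.1)
  })
})
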