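# Statistical toolkit: confusion metrics, ROC/AUC, DeLong tests,
# summary-statistic t/d/chi-square, Mann-Whitney, Fisher exact, KNN
# imputation, outlier flags, BH-FDR, permutation prognostic AUC tests,
# and annual-change regressions.

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return their arithmetic mean.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  (sensitivity + specificity) / 2
}

#' Confusion metrics of a continuous score at a threshold
#'
#' Scores above `threshold` predict the positive class. Balanced accuracy is
#' the mean of sensitivity and specificity.
#'
#' @param scores numeric decision scores.
#' @param truth logical (TRUE = positive class) or 0/1 vector.
#' @param threshold decision threshold (default 0, the SVM convention).
#' @return list with `sensitivity`, `specificity`, `bac`.
#' @export
confusion_metrics <- function(scores, truth, threshold = 0) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2)
    stop("both classes must be present")
  pred <- scores > threshold
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  list(sensitivity = sens, specificity = spec,
       bac = balanced_accuracy(sens, spec))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney U-statistic scaled by `n1*n0`, with ties counted
#' one half — identical to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param truth logical or 0/1 class membership.
#' @return list of class `roc_curve` with `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2) stop("both classes must be present")
  n1 <- sum(truth); n0 <- sum(!truth)
  r <- rank(scores)
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[truth] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!truth] >= t), 0)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

# DeLong placement values: for positives, the fraction of negatives each
# positive beats (ties half); and symmetrically for negatives.
delong_placements <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp),
       auc = mean(cmp))
}

#' DeLong variance of a single AUC
#'
#' @param scores numeric scores.
#' @param truth logical or 0/1 class membership.
#' @return estimated variance of the empirical AUC.
#' @export
auc_variance <- function(scores, truth) {
  truth <- as.logical(truth)
  pl <- delong_placements(scores, truth)
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

#' DeLong test comparing two ROC curves
#'
#' Nonparametric comparison of two AUCs via placement-value covariance.
#' Paired: both score sets are measured on the same subjects and the
#' placement covariances enter the variance of the AUC difference. Unpaired:
#' two independent samples, each with its own labels, and the covariance
#' terms are zero.
#'
#' @param scores_a,scores_b the two score sets.
#' @param truth class membership for `scores_a` (and for `scores_b` when
#'   paired).
#' @param truth_b class membership for `scores_b` (unpaired only).
#' @param paired logical.
#' @return list of class `delong_result` with `auc_a`, `auc_b`, `var_diff`,
#'   `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, truth, truth_b = NULL,
                        paired = TRUE) {
  truth <- as.logical(truth)
  if (paired) {
    stopifnot(length(scores_a) == length(scores_b))
    pa <- delong_placements(scores_a, truth)
    pb <- delong_placements(scores_b, truth)
    m <- length(pa$v10); n <- length(pa$v01)
    s10 <- cov(cbind(pa$v10, pb$v10))
    s01 <- cov(cbind(pa$v01, pb$v01))
    vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
          (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  } else {
    if (is.null(truth_b)) stop("truth_b required for unpaired comparison")
    pa <- delong_placements(scores_a, truth)
    pb <- delong_placements(scores_b, as.logical(truth_b))
    vd <- var(pa$v10) / length(pa$v10) + var(pa$v01) / length(pa$v01) +
          var(pb$v10) / length(pb$v10) + var(pb$v01) / length(pb$v01)
  }
  d <- pa$auc - pb$auc
  if (vd <= 0) {
    z <- if (abs(d) < 1e-12) 0 else NA_real_
    p <- if (abs(d) < 1e-12) 1 else NA_real_
    if (is.na(z)) warning("degenerate DeLong variance; test undefined")
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = vd,
                 z = z, p = p, paired = paired),
            class = "delong_result")
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, computed from
#' group means, SDs and sizes (as printed in demographic tables).
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summaries.
#' @return list with `statistic`, `df`, `p`.
#' @export
welch_t_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) return(list(statistic = 0, df = n1 + n2 - 2, p = 1))
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' Pooled SD weighted by `(n - 1)` per group.
#'
#' @inheritParams welch_t_summary
#' @return Cohen's d (absolute difference over pooled SD, signed by
#'   `m1 - m2`).
#' @export
cohens_d_pooled <- function(m1, sd1, n1, m2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (m1 - m2) / sp
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 count matrix.
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Fisher's exact test of a 2x2 table
#'
#' @param tab 2x2 count matrix.
#' @return list with `p`, `odds_ratio`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contingency table")
  ft <- fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (W), `p`.
#' @export
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Paired t-test with within-subject Cohen's d
#'
#' d is the mean paired difference over the SD of the differences.
#'
#' @param x0,x1 paired measurements (e.g. baseline, follow-up).
#' @return list with `statistic`, `df`, `p`, `d`.
#' @export
paired_t <- function(x0, x1) {
  stopifnot(length(x0) == length(x1))
  d <- x1 - x0
  tt <- t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / sd(d))
}

#' K-nearest-neighbour imputation
#'
#' Missing entries are replaced by the mean of that column over the `k`
#' nearest rows, with distances computed over mutually observed,
#' standardized columns. Columns named in `exclude` (e.g. outcomes) are
#' neither imputed nor used for distances, avoiding outcome leakage.
#'
#' @param x data.frame or matrix of numeric variables.
#' @param k number of neighbours.
#' @param exclude character column names to leave untouched.
#' @return the completed table.
#' @export
knn_impute <- function(x, k = 5, exclude = character()) {
  df <- as.data.frame(x)
  use <- setdiff(names(df), exclude)
  m <- as.matrix(df[use])
  if (any(colSums(!is.na(m)) == 0)) stop("column with all values missing")
  if (sum(complete.cases(m)) < k)
    stop("need at least k complete rows")
  if (!anyNA(m)) return(df)
  ctr <- colMeans(m, na.rm = TRUE)
  scl <- apply(m, 2, sd, na.rm = TRUE)
  scl[scl == 0 | is.na(scl)] <- 1
  zs <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  out <- m
  for (i in which(!complete.cases(m))) {
    miss <- which(is.na(m[i, ]))
    obs <- which(!is.na(m[i, ]))
    d2 <- rowMeans((zs[, obs, drop = FALSE] -
                    matrix(zs[i, obs], nrow(m), length(obs),
                           byrow = TRUE))^2, na.rm = TRUE)
    d2[i] <- Inf
    for (j in miss) {
      donors <- which(!is.na(m[, j]) & is.finite(d2))
      nb <- donors[order(d2[donors])][seq_len(min(k, length(donors)))]
      out[i, j] <- mean(m[nb, j])
    }
  }
  df[use] <- as.data.frame(out)
  df
}

#' Flag statistical outliers beyond k standard deviations
#'
#' Strict inequality: a value at exactly `mean + k*SD` is not flagged.
#'
#' @param values numeric vector.
#' @param k_sd threshold in SD units (default 3).
#' @return logical mask of outliers.
#' @export
flag_outliers <- function(values, k_sd = 3) {
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  !is.na(values) & abs(values - m) > k_sd * s
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, >= raw).
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# rank-based AUC for a fixed positive-index set (fast permutation kernel)
auc_from_ranks <- function(r, pos_idx, n1, n0) {
  (sum(r[pos_idx]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation test of prognostic AUC
#'
#' Tests whether a continuous pattern-expression score predicts a binary
#' outcome: the outcome labels are randomly permuted `n_perm` times, the AUC
#' recomputed each time to form the null distribution, and the observed AUC
#' compared two-sidedly via its distance from 0.5. The add-one estimator
#' keeps p >= 1/(n_perm + 1).
#'
#' @param score numeric scores.
#' @param outcome binary outcome (0/1 or logical).
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @return list of class `permutation_result` with `auc`, `p`, `n_perm`,
#'   `null_auc`.
#' @export
permutation_outcome_auc <- function(score, outcome, n_perm = 5000,
                                    seed = 1L) {
  outcome <- as.logical(outcome)
  keep <- !is.na(score) & !is.na(outcome)
  score <- score[keep]; outcome <- outcome[keep]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome levels must be present")
  r <- rank(score)
  n <- length(score)
  obs <- auc_from_ranks(r, which(outcome), n1, n0)
  with_seed(seed, {
    null_auc <- vapply(seq_len(n_perm), function(i) {
      auc_from_ranks(r, sample.int(n, n1), n1, n0)
    }, 0)
    p <- (1 + sum(abs(null_auc - 0.5) >= abs(obs - 0.5) - 1e-12)) /
      (n_perm + 1)
    structure(list(auc = obs, p = p, n_perm = n_perm, seed = seed,
                   null_auc = null_auc),
              class = "permutation_result")
  })
}

#' Regression of annualized change on annualized change
#'
#' Divides each subject's deltas by their individual follow-up length and
#' regresses annualized `delta_y` on annualized `delta_x`.
#'
#' @param delta_x,delta_y per-subject changes between timepoints.
#' @param followup_years per-subject follow-up length in years.
#' @return list with `slope`, `r_squared`, `p`, `n`.
#' @export
annual_change_regression <- function(delta_x, delta_y, followup_years) {
  stopifnot(length(delta_x) == length(delta_y),
            length(followup_years) %in% c(1, length(delta_x)))
  ax <- delta_x / followup_years
  ay <- delta_y / followup_years
  keep <- is.finite(ax) & is.finite(ay)
  ax <- ax[keep]; ay <- ay[keep]
  if (length(ax) < 3) stop("need at least 3 subjects")
  if (sd(ax) < 1e-12) stop("annualized delta_x is constant")
  fit <- lm(ay ~ ax)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), r_squared = sm$r.squared,
       p = sm$coefficients[2, 4], n = length(ax))
}
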