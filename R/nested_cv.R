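# Repeated nested cross-validation: an outer permutations x folds cycle
# (CV2) assesses generalization; an inner cycle (CV1) nested in each outer
# training partition selects hyperparameters (FWHM, C or nu) by balanced
# accuracy / MAE. Winning inner-fold models form the partition's ensemble.

# stratified fold assignment: within each stratum, shuffled members get
# folds round-robin in a random fold order, so per-fold class proportions
# stay within one subject of the global proportions.
strat_fold_assign <- function(strata, k) {
  n <- length(strata)
  out <- integer(n)
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    if (length(idx) < k)
      stop("stratum '", lev, "' has fewer members (", length(idx),
           ") than folds (", k, ")")
    out[sample(idx)] <- rep(sample.int(k), length.out = length(idx))
  }
  out
}

#' Build a repeated nested cross-validation plan
#'
#' Assigns every subject to one outer test fold per outer permutation, and
#' partitions each outer training set into inner folds, stratified by class
#' label (classification) or by age decile (regression). Deterministic given
#' `seed`.
#'
#' @param y class labels (classification) or continuous target (regression).
#' @param task `"classification"` or `"regression"`.
#' @param outer `c(permutations, folds)` of the outer (CV2) cycle.
#' @param inner `c(permutations, folds)` of the inner (CV1) cycle.
#' @param seed integer RNG seed.
#' @return list of class `cv_plan` with `outer_assign` (n x outer perms
#'   matrix of fold ids) and `inner_assign[[p]][[f]]`, a list holding the
#'   global `train_idx` of the partition and its inner fold-id matrix
#'   (length(train_idx) x inner perms).
#' @export
build_cv_plan <- function(y, task = c("classification", "regression"),
                          outer = c(10, 10), inner = c(10, 5), seed = 1L) {
  task <- match.arg(task)
  n <- length(y)
  strata <- if (task == "classification") {
    as.character(y)
  } else {
    as.character(cut(rank(y, ties.method = "first"),
                     breaks = 10, labels = FALSE))
  }
  with_seed(seed, {
    outer_assign <- matrix(0L, n, outer[1])
    inner_assign <- vector("list", outer[1])
    for (p in seq_len(outer[1])) {
      outer_assign[, p] <- strat_fold_assign(strata, outer[2])
      inner_assign[[p]] <- vector("list", outer[2])
      for (f in seq_len(outer[2])) {
        tr <- which(outer_assign[, p] != f)
        ia <- matrix(0L, length(tr), inner[1])
        for (q in seq_len(inner[1]))
          ia[, q] <- strat_fold_assign(strata[tr], inner[2])
        inner_assign[[p]][[f]] <- list(train_idx = tr, assign = ia)
      }
    }
    structure(list(task = task, n = n, outer = outer, inner = inner,
                   seed = as.integer(seed), outer_assign = outer_assign,
                   inner_assign = inner_assign),
              class = "cv_plan")
  })
}

#' Default SVM hyperparameter grids
#'
#' Soft-margin cost grid for the classifier, nu grid (at fixed cost 1) for
#' the regressor, and the smoothing-kernel FWHM grid.
#'
#' @return list with `cost`, `nu`, `regressor_cost`, `fwhm`,
#'   `regressor_fwhm`.
#' @export
default_hyper_grid <- function() {
  list(cost = c(0.0039, 0.0156, 0.0625, 0.25, 1, 4, 16, 64, 256),
       nu = c(0.2, 0.5, 0.7),
       regressor_cost = 1,
       fwhm = c(4, 6, 8),
       regressor_fwhm = 8)
}

# Fit a linear soft-margin SVM; returns decision function w, b with
# w.x + b > 0 predicting the positive class.
fit_linear_svm <- function(x, y, cost, positive) {
  yf <- factor(ifelse(y == positive, "pos", "neg"), levels = c("neg", "pos"))
  m <- e1071::svm(x, yf, type = "C-classification", kernel = "linear",
                  cost = cost, scale = FALSE)
  pr <- predict(m, x, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # orient decision values toward the positive class
  if (!grepl("^pos", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  w <- drop(t(m$coefs) %*% m$SV)
  f <- drop(x %*% w)
  s <- if (sum(f * dv) < 0) -1 else 1
  w <- s * w
  b <- mean(dv - x %*% w)
  list(w = w, b = b)
}

# Fit a linear nu-SVR; returns w, b with prediction w.x + b.
fit_linear_nusvr <- function(x, y, nu, cost = 1) {
  m <- e1071::svm(x, y, type = "nu-regression", kernel = "linear",
                  nu = nu, cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  pred <- predict(m, x)
  b <- mean(pred - x %*% w)
  list(w = w, b = b)
}

# shared nested-CV engine; `task` switches label handling, model fitting,
# and the selection metric (max BAC vs min MAE).
nested_cv_engine <- function(stack, y, covariates, plan, combos, task,
                             positive = "patient", control = "control",
                             variance_target = 0.8,
                             covreg_on_controls = (task == "classification")) {
  stopifnot(inherits(plan, "cv_plan"), nrow(stack$data) == plan$n,
            length(y) == plan$n)
  covariates <- as.data.frame(covariates)
  fwhms <- sort(unique(vapply(combos, `[[`, 0, "fwhm")))
  smoothed <- lapply(fwhms, function(f) gaussian_smooth(stack, f))
  names(smoothed) <- as.character(fwhms)

  models <- list()
  selection <- list()
  trace <- list()
  cv2_scores <- matrix(NA_real_, plan$n, plan$outer[1])

  for (p in seq_len(plan$outer[1])) {
    for (f in seq_len(plan$outer[2])) {
      part <- plan$inner_assign[[p]][[f]]
      tr <- part$train_idx
      te <- which(plan$outer_assign[, p] == f)
      best <- NULL
      for (cb in combos) {
        sm <- smoothed[[as.character(cb$fwhm)]]
        metrics <- c()
        cand <- list()
        for (q in seq_len(plan$inner[1])) {
          for (g in seq_len(plan$inner[2])) {
            itr <- tr[part$assign[, q] != g]
            ite <- tr[part$assign[, q] == g]
            if (task == "classification" &&
                (length(unique(y[itr])) < 2 || length(unique(y[ite])) < 2)) {
              warning("degenerate inner fold skipped (single class)")
              next
            }
            covreg_idx <- if (covreg_on_controls) {
              itr[y[itr] == control]
            } else itr
            chain <- fit_chain(sm, covariates, itr, covreg_idx,
                               variance_target, fwhm_mm = cb$fwhm)
            feat <- apply_chain(chain, sm, covariates, itr)
            fit <- if (task == "classification") {
              fit_linear_svm(feat, y[itr], cb$cost, positive)
            } else {
              fit_linear_nusvr(feat, y[itr], cb$nu, cb$cost)
            }
            fte <- apply_chain(chain, sm, covariates, ite)
            sc <- drop(fte %*% fit$w + fit$b)
            metric <- if (task == "classification") {
              confusion_metrics(sc, y[ite] == positive)$bac
            } else {
              mean(abs(sc - y[ite]))
            }
            metrics <- c(metrics, metric)
            cand[[length(cand) + 1]] <-
              list(chain = chain, w = fit$w, b = fit$b,
                   fwhm = cb$fwhm, cost = cb$cost, nu = cb$nu,
                   outer_perm = p, outer_fold = f,
                   inner_perm = q, inner_fold = g)
          }
        }
        if (!length(metrics)) next
        m <- mean(metrics)
        trace[[length(trace) + 1]] <- data.frame(
          outer_perm = p, outer_fold = f, fwhm = cb$fwhm,
          cost = cb$cost %||% NA_real_, nu = cb$nu %||% NA_real_,
          inner_metric = m)
        better <- if (is.null(best)) TRUE
          else if (task == "classification") m > best$metric + 1e-12
          else m < best$metric - 1e-12
        if (better) best <- list(metric = m, combo = cb, models = cand)
      }
      if (is.null(best))
        stop("all inner folds degenerate for outer partition (", p, ",", f, ")")
      models <- c(models, best$models)
      selection[[length(selection) + 1]] <- data.frame(
        outer_perm = p, outer_fold = f, fwhm = best$combo$fwhm,
        cost = best$combo$cost, nu = best$combo$nu %||% NA_real_,
        inner_metric = best$metric)
      # outer-test predictions: mean over the partition's winning models
      sm <- smoothed[[as.character(best$combo$fwhm)]]
      sc <- vapply(best$models, function(md) {
        drop(apply_chain(md$chain, sm, covariates, te) %*% md$w + md$b)
      }, numeric(length(te)))
      cv2_scores[te, p] <- rowMeans(matrix(sc, nrow = length(te)))
    }
  }
  structure(
    list(task = task, models = models,
         selection = do.call(rbind, selection),
         trace = do.call(rbind, trace),
         cv2_scores = cv2_scores, y = y, positive = positive,
         grid_shape = stack$grid_shape, voxel_size_mm = stack$voxel_size_mm,
         covariate_names = colnames(covariates),
         variance_target = variance_target, plan_seed = plan$seed,
         outer = plan$outer, inner = plan$inner),
    class = "model_ensemble"
  )
}

#' Train the disorder-vs-control classifier under nested CV
#'
#' For every outer training partition and every (FWHM, cost) combination,
#' fits the in-fold preprocessing chain (covariate regression on the inner
#' training controls, PCA, min-max scaling) plus a linear soft-margin SVM on
#' each inner training set, and scores balanced accuracy on the inner test
#' sets. The combination with maximal mean inner BAC wins; ties break toward
#' smaller cost, then smaller FWHM (more regularization, less smoothing).
#' The winner's inner-fold models are retained as the partition's ensemble
#' and applied to the outer test subjects (mean decision score).
#'
#' @param stack z-normalized [gm_stack()] (see [znorm_dataset()]).
#' @param labels class labels, one per stack row.
#' @param covariates numeric covariate data.frame (e.g. age, sex) for the
#'   nuisance regression.
#' @param plan a [build_cv_plan()] for these labels.
#' @param fwhm_grid,cost_grid hyperparameter grids
#'   (see [default_hyper_grid()]).
#' @param variance_target PCA variance target.
#' @param positive,control labels of the patient and control class.
#' @return a `model_ensemble` (models, selection trace, outer-test decision
#'   scores).
#' @export
train_nested_classifier <- function(stack, labels, covariates, plan,
                                    fwhm_grid = default_hyper_grid()$fwhm,
                                    cost_grid = default_hyper_grid()$cost,
                                    variance_target = 0.8,
                                    positive = "patient",
                                    control = "control") {
  if (length(unique(labels)) != 2) stop("labels must be binary")
  combos <- list()
  for (cost in sort(cost_grid)) for (fw in sort(fwhm_grid))
    combos[[length(combos) + 1]] <- list(fwhm = fw, cost = cost)
  nested_cv_engine(stack, labels, covariates, plan, combos,
                   task = "classification", positive = positive,
                   control = control, variance_target = variance_target)
}

#' Train the brain-age regressor under nested CV
#'
#' As [train_nested_classifier()], but with linear nu-SVR at fixed cost,
#' selection by lowest mean inner MAE, and ties breaking toward smaller nu,
#' then smaller FWHM. The covariate regression is fitted on all inner
#' training rows (the cohort is healthy).
#'
#' @param stack z-normalized [gm_stack()].
#' @param age continuous target (years), one per stack row.
#' @param covariates nuisance covariates (e.g. sex, field strength / site).
#' @param plan a [build_cv_plan()] with `task = "regression"`.
#' @param nu_grid,fwhm_grid,cost hyperparameters.
#' @param variance_target PCA variance target.
#' @return a `model_ensemble` with outer-test predicted ages.
#' @export
train_nested_regressor <- function(stack, age, covariates, plan,
                                   nu_grid = default_hyper_grid()$nu,
                                   fwhm_grid = default_hyper_grid()$regressor_fwhm,
                                   cost = 1, variance_target = 0.8) {
  combos <- list()
  for (nu in sort(nu_grid)) for (fw in sort(fwhm_grid))
    combos[[length(combos) + 1]] <- list(fwhm = fw, nu = nu, cost = cost)
  nested_cv_engine(stack, age, covariates, plan, combos, task = "regression",
                   variance_target = variance_target,
                   covreg_on_controls = FALSE)
}

#' Apply a trained ensemble to an external cohort (OOCV)
#'
#' Every retained model applies its own fitted preprocessing chain and
#' linear decision function; the per-subject score is the arithmetic mean
#' over all models (order-invariant). The external stack must already be
#' z-normalized with its own controls.
#'
#' @param ensemble a trained `model_ensemble`.
#' @param stack external z-normalized [gm_stack()] on the same voxel grid.
#' @param covariates covariate data.frame with the training covariate
#'   columns.
#' @return data.frame of class `prediction_set` with `subject_id` and
#'   `score`; the per-model score matrix is in `attr(, "raw_scores")`.
#' @export
predict_oocv <- function(ensemble, stack, covariates) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  if (!identical(as.integer(stack$grid_shape),
                 as.integer(ensemble$grid_shape)))
    stop("voxel grid mismatch between ensemble and data")
  covariates <- as.data.frame(covariates)
  fwhms <- sort(unique(vapply(ensemble$models, `[[`, 0, "fwhm")))
  smoothed <- lapply(fwhms, function(f) gaussian_smooth(stack, f))
  names(smoothed) <- as.character(fwhms)
  raw <- vapply(ensemble$models, function(md) {
    sm <- smoothed[[as.character(md$fwhm)]]
    drop(apply_chain(md$chain, sm, covariates) %*% md$w + md$b)
  }, numeric(nrow(stack$data)))
  raw <- matrix(raw, nrow = nrow(stack$data))
  out <- data.frame(subject_id = stack$subject_ids,
                    score = rowMeans(raw), stringsAsFactors = FALSE)
  attr(out, "raw_scores") <- raw
  class(out) <- c("prediction_set", class(out))
  out
}

#' Outer-loop (CV2) performance of a trained ensemble
#'
#' Pools each subject's outer-test scores (mean across outer permutations)
#' and reports sensitivity, specificity, BAC and AUC at decision threshold 0
#' for classifiers, or MAE and the prediction-target correlation for
#' regressors.
#'
#' @param ensemble a trained `model_ensemble`.
#' @return list with `predictions` (per-subject aggregated score) plus the
#'   task's metrics.
#' @export
cv2_performance <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  agg <- rowMeans(ensemble$cv2_scores)
  if (ensemble$task == "classification") {
    truth <- ensemble$y == ensemble$positive
    cm <- confusion_metrics(agg, truth)
    list(predictions = agg,
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         bac = cm$bac, auc = roc_auc(agg, truth)$auc)
  } else {
    list(predictions = agg,
         mae = mean(abs(agg - ensemble$y)),
         r = cor(agg, ensemble$y))
  }
}
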