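# Brain-age gap (BrainAGE) computation and age-bias detrending.

#' Brain-age gap per subject
#'
#' `gap = predicted - chronological` (years).
#'
#' @param predicted model-predicted ages.
#' @param chronological chronological ages.
#' @param subject_id optional identifiers.
#' @return data.frame of class `brainage_result` with `subject_id`,
#'   `predicted`, `chronological`, `gap_raw`, and `gap_detrended` (NA until
#'   [apply_detrend()] fills it).
#' @export
brainage_gap <- function(predicted, chronological, subject_id = NULL) {
  if (length(predicted) != length(chronological))
    stop("predicted and chronological ages must be matched")
  if (is.null(subject_id)) subject_id <- seq_along(predicted)
  out <- data.frame(subject_id = subject_id, predicted = predicted,
                    chronological = chronological,
                    gap_raw = predicted - chronological,
                    gap_detrended = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("brainage_result", class(out))
  out
}

#' Fit detrending parameters for the age-dependent prediction bias
#'
#' Brain-age models overestimate young and underestimate old subjects; the
#' correction is the OLS fit of the outer-test (CV2) age residuals
#' `predicted - chronological` on chronological age. The parameters are
#' fitted once on the training cohort's CV2 predictions and applied
#' unchanged to external cohorts.
#'
#' @param predicted,chronological CV2 predictions and true ages
#'   (>= 3 subjects, non-constant age).
#' @return list of class `detrend_params` with `intercept`, `slope`.
#' @export
fit_detrend <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological))
  if (length(predicted) < 3) stop("need at least 3 subjects")
  if (sd(chronological) < 1e-12) stop("constant chronological age")
  fit <- lm(I(predicted - chronological) ~ chronological)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2])),
            class = "detrend_params")
}

#' Apply detrending to brain-age gaps
#'
#' `gap_detrended = gap_raw - (intercept + slope * chronological)`. On the
#' fitting set the OLS slope of the detrended gap on age is zero by
#' construction.
#'
#' @param results a [brainage_gap()] data.frame.
#' @param params a [fit_detrend()] result.
#' @return the results with `gap_detrended` filled in.
#' @export
apply_detrend <- function(results, params) {
  stopifnot(inherits(params, "detrend_params"))
  results$gap_detrended <- results$gap_raw -
    (params$intercept + params$slope * results$chronological)
  results
}
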