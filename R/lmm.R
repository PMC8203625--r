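# Linear mixed models with random subject intercepts for longitudinal
# pattern-expression analyses.

#' Mixed-model interaction test with random subject intercepts
#'
#' Fits `response ~ x * time + covariates + (1 | subject)` by REML and tests
#' the `x:time` interaction with a Satterthwaite F test. `x` may be a group
#' factor (group-by-timepoint interaction) or a continuous expression
#' difference. Marginal R-squared is the fixed-effects variance over the
#' total (fixed + random intercept + residual); conditional R-squared adds
#' the random-intercept variance to the numerator.
#'
#' @param data long-format data.frame (one row per subject-timepoint).
#' @param response,x,time,subject column names.
#' @param covariates character vector of additional fixed-effect columns.
#' @return list of class `lmm_result` with `f`, `df1`, `df2`, `p`,
#'   `coefficients`, `varcomp` (random intercept and residual variance),
#'   `r2_marginal`, `r2_conditional`, `messages` (convergence notes, if
#'   any), and the fitted `model`.
#' @export
lmm_interaction <- function(data, response, x, time, subject,
                            covariates = character()) {
  stopifnot(all(c(response, x, time, subject) %in% names(data)))
  rhs <- c(paste0(x, " * ", time), covariates,
           paste0("(1 | ", subject, ")"))
  form <- reformulate(rhs, response = response)
  msgs <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = data, REML = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  av <- stats::anova(fit)  # lmerTest: Type III, Satterthwaite ddf
  irow <- grep(":", rownames(av))[1]
  if (is.na(irow)) stop("interaction term not found in anova table")

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  X <- lme4::getME(fit, "X")
  var_fix <- var(as.vector(X %*% lme4::fixef(fit)))
  tot <- var_fix + var_re + var_res

  structure(
    list(f = av[irow, "F value"], df1 = av[irow, "NumDF"],
         df2 = av[irow, "DenDF"], p = av[irow, "Pr(>F)"],
         coefficients = lme4::fixef(fit),
         varcomp = c(random_intercept = var_re, residual = var_res),
         r2_marginal = var_fix / tot,
         r2_conditional = (var_fix + var_re) / tot,
         messages = msgs, model = fit),
    class = "lmm_result"
  )
}
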