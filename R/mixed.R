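#' Compare breathing modes with a random-intercept mixed model
#'
#' Fits `rmse ~ mode + (1 | subject_id)` by maximum likelihood to
#' subject-level RMSE values pooled across the two breathing modes
#' (partially crossed designs — subjects present in one or both modes —
#' are supported), and tests the mode fixed effect with a likelihood-ratio
#' test against the no-mode model.
#'
#' @param rmse_table data.frame with columns `subject_id`, `mode`
#'   (both breathing modes must be present) and `rmse`.
#' @param index Spirometric index label carried into the result.
#' @return List of class `mixed_model_result`: `fixed_effect_mode`
#'   (estimate, SE), `p_value` (LRT), `variance_components` (subject
#'   intercept, residual), `index`, `fit` (the lme4 model).
#' @export
compare_modes <- function(rmse_table, index = NA_character_) {
  need <- c("subject_id", "mode", "rmse")
  if (!all(need %in% names(rmse_table)))
    stop_param("rmse_table needs columns: ", paste(need, collapse = ", "))
  modes <- unique(rmse_table$mode)
  if (length(modes) < 2L)
    stop_param("mode contrast undefined: only one breathing mode present")
  df <- rmse_table
  df$mode <- factor(df$mode, levels = BREATHING_MODES)
  # partially crossed designs can leave singleton subjects (or, in the
  # degenerate independent-subjects case, nothing but singletons); the
  # variance component then sits on the boundary rather than erroring
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit1 <- suppressMessages(suppressWarnings(
    lme4::lmer(rmse ~ mode + (1 | subject_id), data = df, REML = FALSE,
               control = ctrl)))
  fit0 <- suppressMessages(suppressWarnings(
    lme4::lmer(rmse ~ 1 + (1 | subject_id), data = df, REML = FALSE,
               control = ctrl)))
  lrt <- 2 * (as.numeric(logLik(fit1)) - as.numeric(logLik(fit0)))
  p <- pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  fe <- lme4::fixef(fit1)
  se <- sqrt(diag(as.matrix(stats::vcov(fit1))))
  vc <- as.data.frame(lme4::VarCorr(fit1))
  tau2 <- vc$vcov[vc$grp == "subject_id"][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  structure(list(
    fixed_effect_mode = c(estimate = unname(fe[2]), se = unname(se[2])),
    p_value = p,
    variance_components = c(subject_intercept = tau2, residual = sigma2),
    index = index, fit = fit1), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_result>%s mode effect %.4g (SE %.4g), LRT p = %.4g\n",
    if (is.na(x$index)) "" else paste0(" ", x$index, ":"),
    x$fixed_effect_mode[["estimate"]], x$fixed_effect_mode[["se"]],
    x$p_value))
  invisible(x)
}
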