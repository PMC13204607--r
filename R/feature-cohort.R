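#' Simulate a feature cohort with a known sparse linear link
#'
#' Generates a [feature_table()] directly (bypassing the signal stages) so
#' the selection and modeling stages can be tested against planted ground
#' truth. Each subject contributes `config$n_cycles_per_subject` breath
#' rows; features are standard normal plus a per-subject random intercept
#' (`feature_subject_sd`), inducing within-subject correlation. The chosen
#' outcome column is
#' `y = intercept + sum(true_coefficients * x) + subject_effect + noise`,
#' with `subject_effect ~ N(0, subject_effect_sd^2)` and
#' `noise ~ N(0, noise_sd^2)`; the remaining targets carry the profile
#' reference values.
#'
#' @param config A [simulation_config()]; `true_coefficients` must be a
#'   named numeric vector over [feature_inventory()] names.
#' @param outcome Which target column receives the planted outcome
#'   (default `"fvc_ref"`).
#' @return A `feature_table` with `n_subjects * n_cycles_per_subject` rows.
#' @export
simulate_feature_cohort <- function(config = simulation_config(),
                                    outcome = "fvc_ref") {
  inv <- feature_inventory()
  beta <- config$true_coefficients %||% setNames(numeric(0), character(0))
  if (length(beta)) {
    bad <- setdiff(names(beta), inv)
    if (length(bad))
      stop_param("unknown feature name(s) in true_coefficients: ",
                 paste(head(bad, 3), collapse = ", "))
  }
  if (!outcome %in% TARGET_NAMES)
    stop_param("`outcome` must be one of: ", paste(TARGET_NAMES, collapse = ", "))
  n_sub <- config$n_subjects
  n_cyc <- config$n_cycles_per_subject
  profiles <- simulate_subject_profiles(n_sub, config$cohort_params,
                                        seed = derive_seed(config$seed, "prof"))
  with_seed(derive_seed(config$seed, "feat"), {
    rows <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      u <- rnorm(length(inv), sd = config$feature_subject_sd)
      X <- matrix(rnorm(n_cyc * length(inv)), n_cyc, length(inv),
                  dimnames = list(NULL, inv))
      X <- sweep(X, 2, u, `+`)
      subj_eff <- rnorm(1, sd = config$subject_effect_sd)
      y <- config$intercept + subj_eff +
        (if (length(beta)) drop(X[, names(beta), drop = FALSE] %*% beta) else 0) +
        rnorm(n_cyc, sd = config$noise_sd)
      prof <- profiles[s, ]
      df <- cbind(
        data.frame(subject_id = prof$subject_id,
                   cycle_id = sprintf("%s_c%02d", prof$subject_id,
                                      seq_len(n_cyc)),
                   mode = config$mode, stringsAsFactors = FALSE),
        as.data.frame(X), profile_covariates(prof),
        prof[1, TARGET_NAMES], row.names = NULL)
      df[[outcome]] <- y
      rows[[s]] <- df
    }
    feature_table(do.call(rbind, rows))
  })
}
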