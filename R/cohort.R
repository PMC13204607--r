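#' Default cohort distribution parameters
#'
#' Mean/SD pairs and category frequencies describing the demographics and
#' reference spirometry of a healthy adult cohort (age ~ 30 y, BMI ~ 24,
#' FVC ~ 4 L, FEV1 ~ 3.2 L, PEF ~ 6.9 L/s). These are the calibration
#' targets of [simulate_subject_profiles()]; all values are configurable.
#'
#' Lower truncation bounds keep draws physiological: age >= 18 y,
#' BMI >= 15 kg/m^2, volumes/flows >= 0.5 (L or L/s).
#'
#' @return A list with elements `age`, `bmi`, `fvc`, `fev1`, `pef` (each
#'   `c(mean, sd)`), `male_prop`, `ethnicity_probs`, `fvc_fev1_cor`.
#' @export
cohort_params_default <- function() {
  list(
    age  = c(mean = 30.3, sd = 6.7),
    bmi  = c(mean = 23.9, sd = 3.3),
    fvc  = c(mean = 4.0,  sd = 1.1),
    fev1 = c(mean = 3.2,  sd = 0.7),
    pef  = c(mean = 6.9,  sd = 1.7),
    male_prop = 8 / 18,
    ethnicity_probs = c(
      "Asian" = 6 / 18, "Caucasian" = 8 / 18,
      "Southeast Asian" = 1 / 18, "Other" = 3 / 18
    ),
    fvc_fev1_cor = 0.9
  )
}

ETHNICITY_LEVELS <- c("Asian", "Caucasian", "Southeast Asian", "Other")

# Truncated normal draw whose *truncated* mean equals `mean`: the location
# parameter is shifted down (uniroot) to undo the mass lost below `lower`.
# Plain truncation of N(30.3, 6.7) at 18 would bias the mean up by ~0.5 y,
# defeating the cohort calibration contract.
rtrunc_calibrated <- function(n, mean, sd, lower) {
  if (sd < 0) stop_param("cohort SDs must be >= 0")
  if (sd == 0) return(rep(mean, n))
  if (mean <= lower)
    stop_param("target mean must exceed the lower truncation bound")
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * dnorm(a) / pnorm(a, lower.tail = FALSE)
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - mean,
                       lower = mean - 6 * sd, upper = mean,
                       extendInt = "upX", tol = 1e-10)$root
  a <- (lower - mu) / sd
  u <- runif(n, pnorm(a), 1)
  mu + sd * qnorm(u)
}

#' Simulate a cohort of subject profiles
#'
#' Draws subject demographics (age, sex, BMI, ethnicity) and reference
#' spirometry (FVC, FEV1, PEF) from configurable distributions. Continuous
#' variables come from truncated normals whose truncated means equal the
#' configured means, so sample moments converge to the configuration. FEV1
#' is drawn correlated with FVC (default r = 0.9) and then clipped to
#' FEV1 <= FVC.
#'
#' @param n_subjects Number of subjects to draw.
#' @param cohort_params Distribution parameters, see [cohort_params_default()].
#' @param seed Integer seed; draws are a pure function of it.
#' @return A data.frame with one row per subject: `subject_id`, `age`,
#'   `sex` ("male"/"female"), `bmi`, `ethnicity`, `fvc_ref`, `fev1_ref`,
#'   `pef_ref`.
#' @export
simulate_subject_profiles <- function(n_subjects,
                                      cohort_params = cohort_params_default(),
                                      seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_param("`n_subjects` must be >= 1")
  n <- as.integer(n_subjects)
  cp <- utils::modifyList(cohort_params_default(), cohort_params)
  for (v in c("age", "bmi", "fvc", "fev1", "pef"))
    if (cp[[v]][["sd"]] < 0) stop_param("cohort SD for ", v, " is negative")

  with_seed(seed, {
    age <- rtrunc_calibrated(n, cp$age[["mean"]], cp$age[["sd"]], 18)
    bmi <- rtrunc_calibrated(n, cp$bmi[["mean"]], cp$bmi[["sd"]], 15)
    fvc <- rtrunc_calibrated(n, cp$fvc[["mean"]], cp$fvc[["sd"]], 0.5)
    rho <- cp$fvc_fev1_cor
    z_fvc <- if (cp$fvc[["sd"]] > 0) (fvc - cp$fvc[["mean"]]) / cp$fvc[["sd"]]
             else rep(0, n)
    fev1 <- cp$fev1[["mean"]] + cp$fev1[["sd"]] *
      (rho * z_fvc + sqrt(1 - rho^2) * rnorm(n))
    fev1 <- pmax(fev1, pmin(0.5, fvc))
    fev1 <- pmin(fev1, fvc)  # physiological constraint FEV1 <= FVC
    pef <- rtrunc_calibrated(n, cp$pef[["mean"]], cp$pef[["sd"]], 0.5)
    sex <- ifelse(runif(n) < cp$male_prop, "male", "female")
    eth <- ETHNICITY_LEVELS[
      1L + findInterval(runif(n), cumsum(cp$ethnicity_probs),
                        rightmost.closed = TRUE)
    ]
    # degenerate (all-SD-zero) cohorts should reproduce the means exactly
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, bmi = bmi, ethnicity = eth,
      fvc_ref = fvc, fev1_ref = fev1, pef_ref = pef,
      stringsAsFactors = FALSE
    )
  })
}
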