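# Per-cycle feature assembly: 185 features per valid breath cycle.
#
# Inventory (fixed order, versioned here):
#   78 acoustic (MFCC summary) features x 2 phases          = 156
#    6 IMU range features (3 axes x {p2p, P95-P5}) x 2 phases =  12
#   17 envelope/timing features (7 per phase + 3 cycle-level) =  17
#                                                       total = 185

MFCC_SUMMARY_NAMES <- local({
  coefs <- sprintf("c%02d", 0:12)
  out <- character(0)
  for (ord in c("mfcc", "d1", "d2"))
    out <- c(out, as.vector(rbind(sprintf("%s_%s_mean", ord, coefs),
                                  sprintf("%s_%s_sd", ord, coefs))))
  out
})

IMU_RANGE_NAMES <- as.vector(t(outer(c("imu_ax", "imu_ay", "imu_az"),
                                     c("p2p", "p95p5"), paste, sep = "_")))

PHASE_TIMING_NAMES <- c("dur_s", "tseng_mean", "tseng_sd", "tseng_max",
                        "tseng_area", "audio_rms", "audio_zcr")

#' The 185-feature inventory
#'
#' Fixed names and order of the per-cycle feature vector: inspiration then
#' expiration MFCC summaries (78 each), inspiration then expiration IMU
#' ranges (6 each), then 17 envelope/timing features.
#'
#' @return Character vector of length 185.
#' @export
feature_inventory <- function() {
  c(paste0("insp_", MFCC_SUMMARY_NAMES), paste0("exp_", MFCC_SUMMARY_NAMES),
    paste0("insp_", IMU_RANGE_NAMES), paste0("exp_", IMU_RANGE_NAMES),
    paste0("insp_", PHASE_TIMING_NAMES), paste0("exp_", PHASE_TIMING_NAMES),
    "cycle_dur_s", "insp_duty", "tseng_area_ratio")
}

#' Feature modality labels
#'
#' Maps each inventory feature to its sensing modality: `"imu"` for the 12
#' accelerometer range features, `"acoustic"` for everything derived from
#' the tracheal sound channel (MFCC summaries and envelope/timing
#' features, which are computed on the sound-energy-segmented cycle).
#'
#' @return Named character vector over [feature_inventory()].
#' @export
feature_modalities <- function() {
  inv <- feature_inventory()
  mod <- ifelse(grepl("_imu_a[xyz]_", inv), "imu", "acoustic")
  setNames(mod, inv)
}

COVARIATE_NAMES <- c("age", "sex", "bmi",
                     "eth_asian", "eth_southeast_asian", "eth_other")
TARGET_NAMES <- c("fvc_ref", "fev1_ref", "pef_ref")

#' IMU range features for one phase segment
#'
#' Per axis: peak-to-peak range (max - min) and a robust range (P95 - P5,
#' linear-interpolation quantiles), 6 features.
#'
#' @param ax,ay,az Acceleration samples (g) within the phase.
#' @return Named numeric vector of 6 features.
#' @export
imu_range_features <- function(ax, ay, az) {
  if (!length(ax) || !length(ay) || !length(az))
    stop_param("empty IMU slice")
  one <- function(v) {
    q <- quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
    c(p2p = max(v) - min(v), p95p5 = q[2] - q[1])
  }
  out <- c(one(ax), one(ay), one(az))
  setNames(out, IMU_RANGE_NAMES)
}

trapz_area <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

zero_crossing_rate <- function(x, duration) {
  if (length(x) < 2L || duration <= 0) return(0)
  sum(diff(x >= 0) != 0) / duration
}

phase_timing_block <- function(lo, hi, tseng, audio_seg, audio_rate) {
  tt <- envelope_times(tseng)
  if (lo < tt[1] - 1 / tseng$rate ||
      hi > tt[length(tt)] + 1 / tseng$rate)
    stop_param("cycle extends past the TSEng envelope")
  sel <- tt >= lo & tt < hi
  if (!any(sel)) stop_param("cycle extends past the TSEng envelope")
  v <- tseng$values[sel]
  dur <- hi - lo
  c(dur_s = dur,
    tseng_mean = mean(v),
    tseng_sd = if (length(v) > 1L) sd(v) else 0,
    tseng_max = max(v),
    tseng_area = trapz_area(tt[sel], v),
    audio_rms = sqrt(mean(audio_seg^2)),
    audio_zcr = zero_crossing_rate(audio_seg, dur))
}

#' Envelope and timing features for one breath cycle
#'
#' Seven features per phase (duration; TSEng mean, SD, max, trapezoidal
#' area; band-passed audio RMS; audio zero-crossing rate) plus three
#' cycle-level features (total duration, inspiratory duty fraction, and
#' the expiration/inspiration TSEng area ratio), 17 in all.
#'
#' @param cycle One-row cycle (`insp_start`, `exp_start`, `cycle_end`).
#' @param tseng A TSEng [envelope()] covering the cycle.
#' @param audio_insp,audio_exp Band-passed audio slices of the two phases.
#' @param audio_rate Audio rate (Hz).
#' @return Named numeric vector of 17 features.
#' @export
envelope_timing_features <- function(cycle, tseng, audio_insp, audio_exp,
                                     audio_rate) {
  t0 <- cycle$insp_start; t1 <- cycle$exp_start; t2 <- cycle$cycle_end
  insp <- phase_timing_block(t0, t1, tseng, audio_insp, audio_rate)
  expb <- phase_timing_block(t1, t2, tseng, audio_exp, audio_rate)
  ratio <- if (abs(insp[["tseng_area"]]) > 1e-12)
    expb[["tseng_area"]] / insp[["tseng_area"]] else 0
  out <- c(setNames(insp, paste0("insp_", PHASE_TIMING_NAMES)),
           setNames(expb, paste0("exp_", PHASE_TIMING_NAMES)),
           cycle_dur_s = t2 - t0,
           insp_duty = (t1 - t0) / (t2 - t0),
           tseng_area_ratio = ratio)
  out
}

slice_by_time <- function(t, lo, hi) which(t >= lo & t < hi)

#' Assemble the 185-feature vector for one breath cycle
#'
#' @param cycle One-row cycle data.frame (`insp_start`, `exp_start`,
#'   `cycle_end`).
#' @param session The [session()] the cycle came from.
#' @param detection The [detect_phases()] result for that session
#'   (supplies the filtered audio and the TSEng envelope).
#' @param params An [mfcc_params()].
#' @return Named numeric vector of exactly 185 finite features, ordered as
#'   [feature_inventory()].
#' @export
assemble_feature_vector <- function(cycle, session, detection,
                                    params = mfcc_params()) {
  rate <- session$audio$rate
  t_audio <- session$audio$t0 +
    (seq_along(session$audio$samples) - 1L) / rate
  fa <- detection$filtered_audio
  ai <- fa[slice_by_time(t_audio, cycle$insp_start, cycle$exp_start)]
  ae <- fa[slice_by_time(t_audio, cycle$exp_start, cycle$cycle_end)]
  ii <- slice_by_time(session$imu$t, cycle$insp_start, cycle$exp_start)
  ie <- slice_by_time(session$imu$t, cycle$exp_start, cycle$cycle_end)
  imu <- session$imu
  out <- c(
    setNames(summarize_mfcc(ai, rate, params),
             paste0("insp_", MFCC_SUMMARY_NAMES)),
    setNames(summarize_mfcc(ae, rate, params),
             paste0("exp_", MFCC_SUMMARY_NAMES)),
    setNames(imu_range_features(imu$ax[ii], imu$ay[ii], imu$az[ii]),
             paste0("insp_", IMU_RANGE_NAMES)),
    setNames(imu_range_features(imu$ax[ie], imu$ay[ie], imu$az[ie]),
             paste0("exp_", IMU_RANGE_NAMES)),
    envelope_timing_features(cycle, detection$envelopes$tseng, ai, ae, rate)
  )
  stopifnot(identical(names(out), feature_inventory()))
  if (any(!is.finite(out))) stop_param("non-finite feature value in cycle")
  out
}

profile_covariates <- function(profile) {
  need <- c("age", "sex", "bmi", "ethnicity")
  miss <- need[!need %in% names(profile)]
  if (length(miss))
    stop_param("profile for subject ", profile$subject_id[1],
               " lacks field(s): ", paste(miss, collapse = ", "))
  data.frame(
    age = profile$age,
    sex = as.numeric(profile$sex == "male"),
    bmi = profile$bmi,
    eth_asian = as.numeric(profile$ethnicity == "Asian"),
    eth_southeast_asian = as.numeric(profile$ethnicity == "Southeast Asian"),
    eth_other = as.numeric(profile$ethnicity == "Other"))
}

#' Build the breath-by-feature modeling table
#'
#' One row per valid breath cycle of each retained session (sessions with
#' fewer than `min_valid_cycles` cycles are excluded entirely), with the
#' 185 features, subject covariates (age; sex coded male = 1; BMI;
#' ethnicity one-hot with Caucasian as the reference level) and the three
#' reference spirometry targets. Cycles whose feature computation fails
#' are dropped with a warning naming the reason.
#'
#' @param sessions Named list of [session()]s.
#' @param detections Named list of [detect_phases()] results, same names.
#' @param params An [mfcc_params()].
#' @param det_params A [detection_params()] (supplies `min_valid_cycles`).
#' @return A data.frame of class `feature_table`: `subject_id`, `cycle_id`,
#'   `mode`, the 185 features, 6 covariates and 3 targets, with no missing
#'   values.
#' @export
build_feature_table <- function(sessions, detections,
                                params = mfcc_params(),
                                det_params = detection_params()) {
  stopifnot(identical(names(sessions), names(detections)))
  rows <- list()
  for (nm in names(sessions)) {
    sess <- sessions[[nm]]
    det <- detections[[nm]]
    cyc <- if (inherits(det, "phase_detection")) det$cycles else det
    if (nrow(cyc) < det_params$min_valid_cycles) next
    cov <- profile_covariates(sess$profile)
    tgt <- sess$profile[1, TARGET_NAMES]
    if (any(is.na(tgt))) stop_param("missing reference targets for ", nm)
    for (k in seq_len(nrow(cyc))) {
      fv <- tryCatch(
        assemble_feature_vector(cyc[k, ], sess, det, params),
        error = function(e) {
          warning(sprintf("dropping cycle %d of %s: %s", k, nm,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(fv)) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = sess$subject_id,
                   cycle_id = sprintf("%s_c%02d", nm, k),
                   mode = sess$mode, stringsAsFactors = FALSE),
        as.data.frame(as.list(fv)), cov, tgt, row.names = NULL)
    }
  }
  if (!length(rows))
    return(feature_table(data.frame()))
  feature_table(do.call(rbind, rows))
}

#' Construct/validate a feature table
#'
#' @param df data.frame with id columns, the 185 features, covariates and
#'   targets.
#' @return The validated `feature_table`.
#' @export
feature_table <- function(df) {
  if (nrow(df)) {
    miss <- setdiff(c(feature_inventory(), COVARIATE_NAMES, TARGET_NAMES),
                    names(df))
    if (length(miss))
      stop_param("feature table lacks column(s): ",
                 paste(head(miss, 5), collapse = ", "))
    num <- df[c(feature_inventory(), COVARIATE_NAMES, TARGET_NAMES)]
    if (any(!is.finite(as.matrix(num))))
      stop_param("feature table contains missing/non-finite values")
  }
  class(df) <- c("feature_table", "data.frame")
  df
}
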