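# Event association and valid-cycle extraction.

#' Associate IMU extrema with TSEng minima into respiratory events
#'
#' Each IMU-Z minimum is paired with the nearest unclaimed TSEng minimum
#' within `association_window` seconds (nearest-first greedy matching, ties
#' to the earlier IMU time); paired minima become inspiration-start events
#' at the IMU extremum time and unpaired IMU minima are dropped. IMU maxima
#' become expiration-start events; with `params$strict_expiration` they too
#' require a nearby TSEng maximum.
#'
#' @param imu_env Envelope of kind `"imu_z"`.
#' @param tseng_env Envelope of kind `"tseng"` on the same rate/time base.
#' @param params A [detection_params()].
#' @return A data.frame of time-ordered events: `time`, `label`
#'   (`"inspiration_start"`/`"expiration_start"`), `imu_extremum_time`,
#'   `tseng_minimum_time` (NA for expiration events).
#' @export
associate_events <- function(imu_env, tseng_env, params = detection_params()) {
  if (imu_env$rate != tseng_env$rate)
    stop_param("envelopes must share the same rate")
  imu_ex <- detect_extrema(imu_env, params)
  ts_ex <- detect_extrema(tseng_env, params)
  insp <- greedy_pair(imu_ex$minima, ts_ex$minima, params$association_window)
  ev <- data.frame(time = numeric(0), label = character(0),
                   imu_extremum_time = numeric(0),
                   tseng_minimum_time = numeric(0))
  if (nrow(insp))
    ev <- rbind(ev, data.frame(time = insp$imu_time,
                               label = "inspiration_start",
                               imu_extremum_time = insp$imu_time,
                               tseng_minimum_time = insp$tseng_time))
  exp_times <- imu_ex$maxima
  if (params$strict_expiration && length(exp_times)) {
    conf <- greedy_pair(exp_times, ts_ex$maxima, params$association_window)
    exp_times <- conf$imu_time
  }
  if (length(exp_times))
    ev <- rbind(ev, data.frame(time = exp_times, label = "expiration_start",
                               imu_extremum_time = exp_times,
                               tseng_minimum_time = NA_real_))
  ev[order(ev$time), , drop = FALSE]
}

# nearest-first greedy one-to-one matching of imu times to tseng times
# within +/- window; ties broken toward the earlier IMU time
greedy_pair <- function(imu_times, tseng_times, window) {
  out <- data.frame(imu_time = numeric(0), tseng_time = numeric(0))
  if (!length(imu_times) || !length(tseng_times)) return(out)
  pairs <- expand.grid(i = seq_along(imu_times), j = seq_along(tseng_times))
  pairs$dt <- abs(imu_times[pairs$i] - tseng_times[pairs$j])
  pairs <- pairs[pairs$dt <= window, , drop = FALSE]
  pairs <- pairs[order(pairs$dt, imu_times[pairs$i]), , drop = FALSE]
  used_i <- logical(length(imu_times))
  used_j <- logical(length(tseng_times))
  keep <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      keep <- c(keep, k)
    }
  }
  res <- pairs[keep, , drop = FALSE]
  res <- res[order(imu_times[res$i]), , drop = FALSE]
  data.frame(imu_time = imu_times[res$i], tseng_time = tseng_times[res$j])
}

#' Extract valid breath cycles from an event sequence
#'
#' A valid cycle is a maximal consecutive pattern inspiration ->
#' expiration -> inspiration, the closing inspiration marking the end of
#' expiration (and possibly opening the next cycle). All other patterns
#' contribute nothing. Intervals are half-open: inspiration `[t0, t1)`,
#' expiration `[t1, t2)`.
#'
#' @param events Time-ordered event data.frame from [associate_events()].
#' @return data.frame with columns `insp_start`, `exp_start`, `cycle_end`.
#' @export
extract_cycles <- function(events) {
  empty <- data.frame(insp_start = numeric(0), exp_start = numeric(0),
                      cycle_end = numeric(0))
  n <- nrow(events)
  if (is.null(n) || n < 3L) return(empty)
  if (is.unsorted(events$time)) stop_param("events must be time-ordered")
  lab <- events$label
  tt <- events$time
  i_ins <- which(lab[seq_len(n - 2L)] == "inspiration_start" &
                 lab[seq_len(n - 2L) + 1L] == "expiration_start" &
                 lab[seq_len(n - 2L) + 2L] == "inspiration_start")
  if (!length(i_ins)) return(empty)
  data.frame(insp_start = as.numeric(tt[i_ins]),
             exp_start = as.numeric(tt[i_ins + 1L]),
             cycle_end = as.numeric(tt[i_ins + 2L]))
}

#' Run the full phase-detection pipeline on a session
#'
#' Conditions both channels, detects and associates extrema, and extracts
#' valid breath cycles. Intermediate envelopes and the filtered audio are
#' returned for QC.
#'
#' @param session A [session()].
#' @param params A [detection_params()].
#' @return List of class `phase_detection`: `cycles`, `events`,
#'   `envelopes` (list `imu_z`, `tseng`), `filtered_audio`.
#' @export
detect_phases <- function(session, params = detection_params()) {
  imu_env <- preprocess_imu(session$imu, params)
  fa <- preprocess_audio(session$audio, params)
  tseng_env <- compute_tseng(fa, session$audio$rate, params,
                             t0 = session$audio$t0)
  events <- associate_events(imu_env, tseng_env, params)
  cycles <- extract_cycles(events)
  structure(list(cycles = cycles, events = events,
                 envelopes = list(imu_z = imu_env, tseng = tseng_env),
                 filtered_audio = fa),
            class = "phase_detection")
}

#' @export
print.phase_detection <- function(x, ...) {
  cat(sprintf("<phase_detection> %d event(s), %d valid cycle(s)\n",
              nrow(x$events), nrow(x$cycles)))
  invisible(x)
}

#' Partition sessions by valid-cycle yield
#'
#' Sessions with at least `min_valid_cycles` valid breath cycles are
#' retained (mirroring the at-least-three-maneuvers validity rule of
#' spirometry guidelines); the rest are rejected.
#'
#' @param results Named list mapping session id to a cycle data.frame (or a
#'   `phase_detection` result).
#' @param params A [detection_params()].
#' @return List with `retained` and `rejected` (disjoint sublists of
#'   `results`) and `counts` (named integer vector).
#' @export
filter_valid_sessions <- function(results, params = detection_params()) {
  counts <- vapply(results, function(r) {
    cyc <- if (inherits(r, "phase_detection")) r$cycles else r
    nrow(cyc)
  }, integer(1))
  keep <- counts >= params$min_valid_cycles
  list(retained = results[keep], rejected = results[!keep], counts = counts)
}

#' Ground-truth event times of an annotated timeline
#'
#' Inspiration onsets are the cycle `insp_start`s plus the final
#' `cycle_end` (the closing inhalation that ends the last expiration);
#' expiration onsets are the `exp_start`s.
#'
#' @param timeline A [breath_timeline()].
#' @return List with numeric vectors `insp` and `exp` (times, s).
#' @export
annotation_events <- function(timeline) {
  cyc <- timeline$cycles
  if (!nrow(cyc)) return(list(insp = numeric(0), exp = numeric(0)))
  list(insp = c(cyc$insp_start, cyc$cycle_end[nrow(cyc)]),
       exp = cyc$exp_start)
}

#' Score detected events against an annotated timeline
#'
#' Greedy one-to-one matching of detected inspiration/expiration events to
#' the annotated onsets within a time tolerance; recall is matched over
#' annotated, precision matched over detected.
#'
#' @param events Event data.frame from [associate_events()].
#' @param timeline The ground-truth [breath_timeline()].
#' @param tol Matching tolerance (s, default 0.5).
#' @return List with `recall`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
score_events <- function(events, timeline, tol = 0.5) {
  truth <- annotation_events(timeline)
  det <- list(
    insp = events$time[events$label == "inspiration_start"],
    exp = events$time[events$label == "expiration_start"])
  n_matched <- 0L
  for (lab in c("insp", "exp"))
    n_matched <- n_matched + nrow(greedy_pair(det[[lab]], truth[[lab]], tol))
  n_true <- length(truth$insp) + length(truth$exp)
  n_det <- length(det$insp) + length(det$exp)
  list(recall = if (n_true) n_matched / n_true else NA_real_,
       precision = if (n_det) n_matched / n_det else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_matched)
}
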