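#' Default breath-maneuver timing parameters
#'
#' Phase-duration distributions (seconds) for the two guided maneuvers:
#' `low_effort` (slow deep inhalation, gentle nasal exhalation — long
#' expirations) and `forceful` (deep inhalation, sharp rapid mouth
#' exhalation — short loud expirations). `exp` is the audible expiratory
#' airflow; `pause` is the silent relaxation tail that completes the
#' expiration interval (the next inhalation marks its end, matching the
#' segmentation convention). Only the ordering (forceful expirations
#' shorter/louder) is contractual; the magnitudes are configurable
#' simulator conventions.
#'
#' @param mode `"low_effort"` or `"forceful"`.
#' @return List with `insp`, `exp`, `pause` (each `c(mean, sd, min, max)`),
#'   plus `lead_in` and `tail` paddings in seconds.
#' @export
maneuver_params_default <- function(mode) {
  check_mode(mode)
  if (mode == "low_effort") {
    list(
      insp  = c(mean = 2.5, sd = 0.4, min = 1.6, max = 4.0),
      exp   = c(mean = 3.5, sd = 0.5, min = 1.8, max = 5.5),
      pause = c(mean = 1.2, sd = 0.2, min = 0.6, max = 1.8),
      lead_in = 1.2, tail = 1.2
    )
  } else {
    list(
      insp  = c(mean = 1.8, sd = 0.3, min = 1.6, max = 3.0),
      exp   = c(mean = 1.2, sd = 0.2, min = 0.7, max = 1.9),
      pause = c(mean = 1.0, sd = 0.2, min = 0.5, max = 1.6),
      lead_in = 1.2, tail = 1.2
    )
  }
}

rdur <- function(n, p) pmin(pmax(rnorm(n, p[["mean"]], p[["sd"]]),
                                 p[["min"]]), p[["max"]])

#' Simulate a ground-truth breath timeline
#'
#' Draws `n_cycles` ordered, contiguous breath cycles: each inspiration
#' interval is followed by an expiration interval whose end is the next
#' inspiration onset (the expiration interval comprises the audible
#' exhalation plus a silent relaxation tail). The recording opens on the
#' silent tail of a previous, unannotated breath and closes on the onset
#' of a next inhalation at `cycle_end` of the last cycle, so every
#' annotated event is flanked by signal on both sides. Cycle boundary
#' times are the annotation ground truth against which phase detection is
#' scored.
#'
#' @param mode Maneuver type, `"low_effort"` or `"forceful"`.
#' @param n_cycles Number of breath cycles (>= 1).
#' @param seed Integer seed.
#' @param params Timing parameters, see [maneuver_params_default()].
#' @return A `breath_timeline`: list with `cycles` (data.frame
#'   `insp_start`, `exp_start`, `cycle_end` in seconds), `mode`, `duration`.
#' @export
simulate_breath_timeline <- function(mode, n_cycles, seed = 1L,
                                     params = maneuver_params_default(mode)) {
  check_mode(mode)
  if (!is.numeric(n_cycles) || n_cycles < 1)
    stop_param("`n_cycles` must be >= 1")
  n <- as.integer(n_cycles)
  with_seed(seed, {
    insp <- rdur(n, params$insp)
    expd <- rdur(n, params$exp)
    pause <- rdur(n, params$pause)
    insp_start <- params$lead_in +
      c(0, cumsum((insp + expd + pause)[-n]))[seq_len(n)]
    exp_start <- insp_start + insp
    exp_sound_end <- exp_start + expd
    # next inhalation onset closes each cycle (exactly, for contiguity)
    cycle_end <- c(insp_start[-1], exp_sound_end[n] + pause[n])
    tl <- breath_timeline(
      cycles = data.frame(insp_start = insp_start, exp_start = exp_start,
                          cycle_end = cycle_end),
      mode = mode,
      duration = cycle_end[n] + params$tail
    )
    tl$exp_sound_end <- exp_sound_end
    tl$pre_roll_end <- min(0.5, params$lead_in / 2)
    tl
  })
}

#' Construct/validate a breath timeline
#'
#' @param cycles data.frame with `insp_start`, `exp_start`, `cycle_end` (s).
#' @param mode Maneuver type.
#' @param duration Total recording duration (s).
#' @return A validated `breath_timeline` object.
#' @export
breath_timeline <- function(cycles, mode, duration) {
  check_mode(mode)
  stopifnot(is.data.frame(cycles),
            all(c("insp_start", "exp_start", "cycle_end") %in% names(cycles)))
  if (nrow(cycles)) {
    with(cycles, {
      if (any(!(insp_start < exp_start & exp_start < cycle_end)))
        stop_param("each cycle must satisfy insp_start < exp_start < cycle_end")
      if (any(insp_start < 0) || any(cycle_end > duration))
        stop_param("cycle times must lie within [0, duration]")
      if (nrow(cycles) > 1L &&
          any(diff(insp_start) <= 0 |
              head(cycle_end, -1) > tail(insp_start, -1) + 1e-9))
        stop_param("cycles must be ordered and non-overlapping")
    })
  }
  structure(list(cycles = cycles, mode = mode, duration = duration),
            class = "breath_timeline")
}

#' @export
print.breath_timeline <- function(x, ...) {
  cat(sprintf("<breath_timeline> %s, %d cycle(s), %.1f s\n",
              x$mode, nrow(x$cycles), x$duration))
  invisible(x)
}
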