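# Prominence/distance peak detection on conditioned envelopes.

# strict local maxima; plateaus contribute their first sample
local_maxima_idx <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence: height above the higher of the two bases, where
# each base is the minimum between the peak and the nearest higher terrain
# (or the signal edge)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    lv <- x[p]
    i <- p
    left_min <- lv
    while (i > 1L) {
      i <- i - 1L
      if (x[i] > lv) break
      if (x[i] < left_min) left_min <- x[i]
    }
    i <- p
    right_min <- lv
    n <- length(x)
    while (i < n) {
      i <- i + 1L
      if (x[i] > lv) break
      if (x[i] < right_min) right_min <- x[i]
    }
    lv - max(left_min, right_min)
  }, numeric(1))
}

# enforce minimum spacing, preferring higher prominence then earlier time
enforce_distance <- function(idx, prom, min_samples) {
  if (!length(idx)) return(integer(0))
  ord <- order(-prom, idx)
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(idx[kept] - idx[k]) >= min_samples))
      kept <- c(kept, k)
  }
  sort(idx[kept])
}

find_peaks_prominence <- function(x, min_prominence, min_samples) {
  cand <- local_maxima_idx(x)
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  keep <- prom >= min_prominence
  enforce_distance(cand[keep], prom[keep], min_samples)
}

#' Detect envelope extrema
#'
#' Local maxima and minima of a conditioned envelope, retained when their
#' topographic prominence reaches `prominence_frac_iqr` times the
#' envelope's interquartile range and thinned to a minimum pairwise spacing
#' of `min_peak_distance` seconds (higher-prominence peaks win ties, then
#' earlier ones). Minima are maxima of the negated signal.
#'
#' @param env An [envelope()].
#' @param params A [detection_params()].
#' @return List with numeric vectors `maxima` and `minima` (times, s).
#' @export
detect_extrema <- function(env, params = detection_params()) {
  x <- env$values
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  if (iqr == 0) {
    warning("constant envelope (IQR = 0): no extrema detected", call. = FALSE)
    return(list(maxima = numeric(0), minima = numeric(0)))
  }
  thr <- params$prominence_frac_iqr * iqr
  dmin <- params$min_peak_distance * env$rate
  tt <- envelope_times(env)
  list(maxima = tt[find_peaks_prominence(x, thr, dmin)],
       minima = tt[find_peaks_prominence(-x, thr, dmin)])
}
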