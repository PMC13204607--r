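# Mel-frequency cepstral coefficients for breath-segment audio.

#' MFCC extraction parameters
#'
#' @param n_coeffs Number of cepstral coefficients kept (13).
#' @param frame_len Frame length (s, default 25 ms).
#' @param hop Hop size (s, default 10 ms).
#' @param n_mels Number of triangular mel filters (HTK mel scale).
#' @param mel_fmin,mel_fmax Filterbank frequency range (Hz); `mel_fmax`
#'   defaults to half the audio rate at compute time.
#' @param log_floor Floor applied to filterbank energies before the log.
#' @param delta_halfwidth Half-width K of the regression-delta window.
#' @param include_c0 Keep the DC cepstral term (coefficients c0..c12);
#'   `FALSE` selects c1..c13 instead.
#' @return An `mfcc_params` list.
#' @export
mfcc_params <- function(n_coeffs = 13L, frame_len = 0.025, hop = 0.010,
                        n_mels = 26L, mel_fmin = 0, mel_fmax = NULL,
                        log_floor = 1e-10, delta_halfwidth = 2L,
                        include_c0 = TRUE) {
  if (n_coeffs > n_mels) stop_param("n_coeffs must be <= n_mels")
  if (!(frame_len > hop && hop > 0)) stop_param("need frame_len > hop > 0")
  structure(list(n_coeffs = as.integer(n_coeffs), frame_len = frame_len,
                 hop = hop, n_mels = as.integer(n_mels), mel_fmin = mel_fmin,
                 mel_fmax = mel_fmax, log_floor = log_floor,
                 delta_halfwidth = as.integer(delta_halfwidth),
                 include_c0 = isTRUE(include_c0)),
            class = "mfcc_params")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, fft_size, rate, fmin, fmax) {
  edges_mel <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  bin_freqs <- (0:(fft_size %/% 2L)) * rate / fft_size
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- edges_hz[m]; ce <- edges_hz[m + 1L]; hi <- edges_hz[m + 2L]
    up <- bin_freqs >= lo & bin_freqs <= ce
    dn <- bin_freqs > ce & bin_freqs <= hi
    fb[m, up] <- (bin_freqs[up] - lo) / max(ce - lo, .Machine$double.eps)
    fb[m, dn] <- (hi - bin_freqs[dn]) / max(hi - ce, .Machine$double.eps)
  }
  fb
}

# orthonormal DCT-II matrix (k x M): rows are cosine basis vectors
dct_matrix <- function(k_idx, M) {
  outer(k_idx, seq_len(M), function(k, m) {
    w <- ifelse(k == 0, sqrt(1 / M), sqrt(2 / M))
    w * cos(pi * k * (m - 0.5) / M)
  })
}

#' Compute static MFCCs for an audio segment
#'
#' Frames the segment (Hamming window), takes the magnitude-squared
#' spectrum (FFT size = next power of two at or above the frame length),
#' applies an HTK-scale triangular mel filterbank, logs the energies with a
#' floor, and projects onto an orthonormal type-II cosine basis, keeping
#' coefficients c0..c12.
#'
#' @param segment Numeric audio samples (band-passed breath-phase slice).
#' @param rate Sampling rate (Hz).
#' @param params An [mfcc_params()].
#' @return Matrix of `n_frames x n_coeffs` with class `mfcc_matrix`,
#'   attribute `order = "static"`. Frame count is
#'   `floor((N - frame_samples) / hop_samples) + 1`.
#' @export
compute_mfcc <- function(segment, rate, params = mfcc_params()) {
  frame_n <- round(params$frame_len * rate)
  hop_n <- round(params$hop * rate)
  N <- length(segment)
  if (N < frame_n) stop_param("segment shorter than one MFCC frame")
  n_frames <- (N - frame_n) %/% hop_n + 1L
  fft_size <- 2^ceiling(log2(frame_n))
  fmax <- params$mel_fmax %||% (rate / 2)
  fb <- mel_filterbank(params$n_mels, fft_size, rate, params$mel_fmin, fmax)
  k_idx <- if (params$include_c0) 0:(params$n_coeffs - 1L)
           else seq_len(params$n_coeffs)
  dct <- dct_matrix(k_idx, params$n_mels)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_n - 1L)) / (frame_n - 1L))
  starts <- (seq_len(n_frames) - 1L) * hop_n
  frames <- matrix(segment[outer(seq_len(frame_n), starts, `+`)],
                   nrow = frame_n)
  frames <- frames * win
  padded <- rbind(frames, matrix(0, fft_size - frame_n, n_frames))
  spec <- Mod(stats::mvfft(padded))^2
  spec <- spec[seq_len(fft_size %/% 2L + 1L), , drop = FALSE]
  loge <- log(pmax(fb %*% spec, params$log_floor))
  out <- t(dct %*% loge)
  colnames(out) <- sprintf("c%02d", k_idx)
  structure(out, class = c("mfcc_matrix", "matrix"), order = "static")
}

#' Regression delta of an MFCC matrix
#'
#' Standard regression derivative over frames,
#' `delta_t = sum_k k (c_{t+k} - c_{t-k}) / (2 sum_k k^2)` with
#' `k = 1..delta_halfwidth` and edge frames replicated. Applied to a static
#' matrix it yields first-order deltas; applied twice, delta-deltas. A
#' single-frame input yields zeros.
#'
#' @param m An `mfcc_matrix`.
#' @param params An [mfcc_params()].
#' @return An `mfcc_matrix` of the next derivative order.
#' @export
compute_delta <- function(m, params = mfcc_params()) {
  K <- params$delta_halfwidth
  n <- nrow(m)
  ord <- attr(m, "order")
  next_ord <- switch(ord, static = "delta", delta = "delta_delta",
                     delta_delta = "delta3", "delta")
  if (n == 1L) {
    out <- m * 0
  } else {
    idx <- function(i) pmin(pmax(i, 1L), n)  # edge replication
    denom <- 2 * sum((1:K)^2)
    out <- matrix(0, n, ncol(m))
    for (k in seq_len(K)) {
      out <- out + k * (m[idx(seq_len(n) + k), , drop = FALSE] -
                          m[idx(seq_len(n) - k), , drop = FALSE])
    }
    out <- out / denom
    colnames(out) <- colnames(m)
  }
  structure(out, class = c("mfcc_matrix", "matrix"), order = next_ord)
}

#' Summary MFCC features for one breath-phase segment
#'
#' Mean and standard deviation (n-1 denominator; 0 for a single frame)
#' over frames of each of the 13 coefficients at the three derivative
#' orders (static, delta, delta-delta): 13 x 3 x 2 = 78 named features.
#'
#' @inheritParams compute_mfcc
#' @return Named numeric vector of 78 features, in fixed order
#'   (`mfcc_c00_mean` ... `d2_c12_sd`).
#' @export
summarize_mfcc <- function(segment, rate, params = mfcc_params()) {
  m0 <- compute_mfcc(segment, rate, params)
  m1 <- compute_delta(m0, params)
  m2 <- compute_delta(m1, params)
  orders <- list(mfcc = m0, d1 = m1, d2 = m2)
  out <- numeric(0)
  for (ord in names(orders)) {
    m <- orders[[ord]]
    mu <- colMeans(m)
    sdv <- if (nrow(m) > 1L) apply(m, 2, sd) else rep(0, ncol(m))
    v <- as.vector(rbind(mu, sdv))
    names(v) <- as.vector(rbind(
      sprintf("%s_%s_mean", ord, colnames(m)),
      sprintf("%s_%s_sd", ord, colnames(m))))
    out <- c(out, v)
  }
  out
}
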