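# Mono 16-bit PCM WAV input/output (RIFF), implemented with readBin/
# writeBin. Readers reject rather than coerce malformed files.

#' Read a mono PCM16 WAV file
#'
#' @param path Path to a RIFF/WAVE file, mono, 16-bit PCM.
#' @return An [audio_recording()] with amplitudes in [-1, 1].
#' @export
read_audio <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_param("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_param("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) stop_param("truncated WAV file: ", path)
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      if (length(raw_fmt) < 16) stop_param("truncated WAV fmt chunk: ", path)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2,
                           signed = FALSE, endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
      if (length(data) < sz) stop_param("truncated WAV data chunk: ", path)
      break
    } else {
      skipped <- readBin(con, "raw", sz)
      if (length(skipped) < sz) stop_param("truncated WAV file: ", path)
    }
  }
  if (is.null(fmt) || is.null(data))
    stop_param("missing fmt/data chunk in WAV file: ", path)
  if (fmt$audio_format != 1L) stop_param("only PCM WAV is supported")
  if (fmt$channels != 1L) stop_param("only mono WAV is supported")
  if (fmt$bits != 16L) stop_param("only 16-bit WAV is supported")
  ints <- readBin(data, "integer", n = length(data) %/% 2L, size = 2,
                  signed = TRUE, endian = "little")
  audio_recording(ints / 32767, fmt$rate)
}

#' Write a mono PCM16 WAV file
#'
#' Amplitudes are clamped to [-1, 1] and quantized to 16 bits; a
#' write/read round trip preserves sample count, rate, and amplitudes to
#' within one quantization step.
#'
#' @param rec An [audio_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audio <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- pmin(pmax(rec$samples, -1), 1)
  ints <- as.integer(round(x * 32767))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(round(rec$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rec$rate)) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
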