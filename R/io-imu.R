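# IMU CSV input/output and session manifests. CSV dialect: comma, dot
# decimal, required header `t_s,ax_g,ay_g,az_g`.

IMU_HEADER <- c("t_s", "ax_g", "ay_g", "az_g")

#' Read a tri-axial IMU CSV
#'
#' @param path CSV with header `t_s,ax_g,ay_g,az_g`; time stamps must be
#'   strictly increasing. Rate is inferred from the median time step.
#' @return An [imu_recording()].
#' @export
read_imu <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), IMU_HEADER))
    stop_param("IMU CSV must have header ", paste(IMU_HEADER, collapse = ","))
  if (!all(vapply(df, is.numeric, logical(1))))
    stop_param("IMU CSV columns must be numeric")
  if (nrow(df) > 1L && any(diff(df$t_s) <= 0))
    stop_param("IMU time stamps must be strictly increasing")
  imu_recording(t = df$t_s, ax = df$ax_g, ay = df$ay_g, az = df$az_g)
}

#' Write a tri-axial IMU CSV
#'
#' Values are written with 9 significant digits, so a round trip is
#' lossless at that precision.
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t_s = signif(rec$t, 9), ax_g = signif(rec$ax, 9),
                   ay_g = signif(rec$ay, 9), az_g = signif(rec$az, 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a breath-timeline annotation as JSON
#'
#' @param timeline A [breath_timeline()].
#' @param path Output path.
#' @param subject_id Subject identifier stored in the file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(timeline, path, subject_id = NA_character_) {
  jsonlite::write_json(
    list(subject_id = subject_id, mode = timeline$mode,
         duration = timeline$duration,
         cycles = timeline$cycles),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a breath-timeline annotation JSON
#'
#' @param path Annotation file written by [write_annotation()].
#' @return A [breath_timeline()].
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cyc <- as.data.frame(j$cycles)
  breath_timeline(cycles = cyc[c("insp_start", "exp_start", "cycle_end")],
                  mode = j$mode, duration = j$duration)
}

#' Write a session (audio, IMU, manifest, optional annotation) to a directory
#'
#' @param sess A [session()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest JSON, invisibly.
#' @export
write_session <- function(sess, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sid <- sess$subject_id
  write_audio(sess$audio, file.path(dir, paste0(sid, "_audio.wav")))
  write_imu(sess$imu, file.path(dir, paste0(sid, "_imu.csv")))
  manifest <- list(subject_id = sid, mode = sess$mode,
                   audio = paste0(sid, "_audio.wav"),
                   imu = paste0(sid, "_imu.csv"),
                   profile = as.list(sess$profile[1, ]))
  if (!is.null(sess$annotation)) {
    ann <- paste0(sid, "_annotation.json")
    write_annotation(sess$annotation, file.path(dir, ann), subject_id = sid)
    manifest$annotation <- ann
  }
  mpath <- file.path(dir, paste0(sid, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Load a session from a JSON manifest
#'
#' The manifest names the audio and IMU files (paths relative to the
#' manifest), the maneuver mode, the subject profile fields, and optionally
#' an annotation file.
#'
#' @param manifest_path Path to the manifest JSON.
#' @return A [session()]; `annotation` is `NULL` when the manifest lists
#'   none.
#' @export
load_session <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  for (f in c("subject_id", "mode", "audio", "imu", "profile"))
    if (is.null(m[[f]])) stop_param("manifest lacks required field `", f, "`")
  if (!(m$mode %in% BREATHING_MODES))
    stop_param("manifest has unknown mode: ", m$mode)
  audio <- read_audio(file.path(base, m$audio))
  imu <- read_imu(file.path(base, m$imu))
  ann <- if (!is.null(m$annotation))
    read_annotation(file.path(base, m$annotation)) else NULL
  profile <- as.data.frame(m$profile, stringsAsFactors = FALSE)
  session(subject_id = m$subject_id, mode = m$mode, audio = audio, imu = imu,
          profile = profile, annotation = ann)
}
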