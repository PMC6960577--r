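#' Write a flight session as per-modality CSV files
#'
#' Emits `<id>_hr.csv`, `<id>_gsr.csv` (columns `time_s`, `value`),
#' `<id>_eeg.csv` (`time_s` plus one column per channel), `<id>_face.csv`
#' (`time_s` plus the five emotion columns) and `<id>_schedule.csv`
#' (`task`, `t_start`, `t_end`).
#'
#' @param session a `flight_session`.
#' @param dir output directory, created if missing.
#' @return invisibly, the session id.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "flight_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- session$session_id
  w <- function(df, suffix)
    utils::write.csv(df, file.path(dir, paste0(id, "_", suffix, ".csv")),
                     row.names = FALSE)
  w(data.frame(time_s = time_points(session$hr), value = session$hr$values),
    "hr")
  w(data.frame(time_s = time_points(session$gsr), value = session$gsr$values),
    "gsr")
  eeg <- data.frame(time_s = time_points(session$eeg[[1]]))
  for (ch in names(session$eeg)) eeg[[ch]] <- session$eeg[[ch]]$values
  w(eeg, "eeg")
  fs_face <- attr(session$face, "fs")
  face <- data.frame(time_s = (seq_len(nrow(session$face)) - 1L) / fs_face)
  for (e in EMOTIONS) face[[e]] <- session$face[, e]
  w(face, "face")
  w(session$schedule, "schedule")
  invisible(id)
}

#' Read a flight session from per-modality CSV files
#'
#' Inverse of [write_session()]. The latent ground-truth trace is not part
#' of the on-disk format, so round-tripped sessions have `latent = NULL`.
#'
#' @param dir directory containing the CSV files.
#' @param id session id (file prefix).
#' @return a `flight_session`.
#' @export
read_session <- function(dir, id) {
  r <- function(suffix)
    utils::read.csv(file.path(dir, paste0(id, "_", suffix, ".csv")))
  fs_of <- function(t) {
    f <- 1 / stats::median(diff(t))
    if (abs(f - round(f)) < 1e-3) round(f) else f   # undo CSV rounding
  }
  hr_df <- r("hr"); gsr_df <- r("gsr"); eeg_df <- r("eeg"); face_df <- r("face")
  eeg <- lapply(EEG_CHANNELS, function(ch)
    time_series(eeg_df[[ch]], fs_of(eeg_df$time_s), paste0("eeg:", ch)))
  names(eeg) <- EEG_CHANNELS
  face <- as.matrix(face_df[, EMOTIONS, drop = FALSE])
  attr(face, "fs") <- fs_of(face_df$time_s)
  structure(
    list(session_id = id,
         hr = time_series(hr_df$value, fs_of(hr_df$time_s), "hr"),
         gsr = time_series(gsr_df$value, fs_of(gsr_df$time_s), "gsr"),
         eeg = eeg, face = face,
         schedule = r("schedule"), latent = NULL),
    class = "flight_session"
  )
}

#' Write a cohort of sessions to a directory
#'
#' @param cohort list of `flight_session` objects.
#' @param dir output directory.
#' @return invisibly, the session ids written.
#' @export
write_cohort <- function(cohort, dir) {
  ids <- vapply(cohort, function(s) write_session(s, dir), character(1))
  invisible(ids)
}

#' Read every session found in a cohort directory
#'
#' Sessions are discovered from the `*_schedule.csv` files.
#'
#' @param dir directory written by [write_cohort()].
#' @return named list of `flight_session` objects.
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "_schedule\\.csv$")
  ids <- sub("_schedule\\.csv$", "", files)
  if (length(ids) == 0L) stop("no sessions found in ", dir)
  cohort <- lapply(ids, function(id) read_session(dir, id))
  names(cohort) <- ids
  cohort
}
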