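#' Write a raw recording as signal CSV plus JSON metadata sidecar
#'
#' The CSV has header \code{t,ecg,z} (time in seconds on a uniform grid);
#' the sidecar \code{<stem>.json} carries \code{subject_id},
#' \code{posture}, \code{fs}, \code{group}, \code{sex}.
#'
#' @param rec a \code{raw_recording}.
#' @param path output CSV path (sidecar written next to it).
#' @return invisibly, the CSV path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- length(rec$ecg)
  df <- data.frame(t = (seq_len(n) - 1L) / rec$fs,
                   ecg = rec$ecg, z = rec$impedance)
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, posture = rec$posture,
               fs = rec$fs, group = rec$group, sex = rec$sex)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a raw recording from signal CSV + JSON sidecar
#'
#' Validates the time column (uniform grid consistent with the sidecar's
#' sampling rate) and the minimum duration for analysis entry (60 s).
#'
#' @param path CSV path written by \code{\link{write_recording}} (or any
#'   file in that format).
#' @return a \code{raw_recording}.
#' @export
read_recording <- function(path) {
  df <- read.csv(path)
  if (!all(c("t", "ecg", "z") %in% names(df))) {
    stop("signal CSV must have columns t, ecg, z", call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  fs <- as.numeric(meta$fs)
  if (!isTRUE(fs > 0)) stop("sidecar must state a positive fs", call. = FALSE)
  dt <- diff(df$t)
  if (length(dt) && (max(abs(dt - 1 / fs)) > 1e-6)) {
    stop("time column is not a uniform grid at the stated fs", call. = FALSE)
  }
  dur <- nrow(df) / fs
  if (dur < 60) stop("recording shorter than 60 s; below analysis entry", call. = FALSE)
  if (length(df$ecg) != length(df$z)) stop("channel length mismatch", call. = FALSE)
  structure(list(subject_id = meta$subject_id %||% "unknown",
                 posture = meta$posture %||% "supine",
                 fs = fs, ecg = df$ecg, impedance = df$z,
                 group = meta$group %||% "control",
                 sex = meta$sex %||% "M",
                 duration = dur, truth = NULL),
            class = "raw_recording")
}

#' Write preprocessing annotations alongside a recording
#'
#' Emits \code{<stem>_rpeaks.csv} (column \code{t_rpeak}) and
#' \code{<stem>_phases.csv} (columns \code{t}, \code{phase}).
#'
#' @param path the recording's CSV path (used as the stem).
#' @param r_peaks \code{rpeak_series}.
#' @param phases \code{breath_phase_series}.
#' @param fs sampling rate of the phase stream.
#' @return invisibly, the two paths written.
#' @export
write_annotations <- function(path, r_peaks, phases, fs) {
  stem <- sub("\\.csv$", "", path)
  p1 <- paste0(stem, "_rpeaks.csv")
  p2 <- paste0(stem, "_phases.csv")
  write.csv(data.frame(t_rpeak = as.numeric(r_peaks)), p1, row.names = FALSE)
  write.csv(data.frame(t = (seq_along(phases) - 1L) / fs,
                       phase = as.integer(phases)), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
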