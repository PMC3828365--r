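#' Single-session multichannel recording
#'
#' Container for one recording session of one mouse: frontal cortical EEG,
#' hippocampal LFP and neck EMG traces (microvolts) sampled at `fs_signal`,
#' plus a 2-D position track (cm) sampled at `fs_position`.
#'
#' @param mouse_id Character scalar identifying the animal.
#' @param genotype `"R6/1"` or `"WT"`.
#' @param age_weeks Positive number; age at recording in weeks.
#' @param channels Named list of numeric vectors in microvolts. Must contain
#'   at least `frontal_eeg`, `hippocampus_lfp` and `emg`; all channels must
#'   have equal length `round(duration_s * fs_signal)`.
#' @param fs_signal Sampling rate of the signal channels, samples/s.
#' @param position Two-column numeric matrix (x, y) in cm, sampled at
#'   `fs_position`.
#' @param fs_position Sampling rate of the position track, samples/s;
#'   must not exceed `fs_signal`.
#' @param duration_s Session duration in seconds (> 0). Time is 0-based
#'   seconds from session start.
#'
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(mouse_id, genotype, age_weeks, channels,
                              fs_signal = 2000, position = NULL,
                              fs_position = 50, duration_s) {
  genotype <- match.arg(genotype, c("R6/1", "WT"))
  stopifnot(is.character(mouse_id), length(mouse_id) == 1L,
            is.numeric(age_weeks), age_weeks > 0,
            is.numeric(duration_s), duration_s > 0,
            fs_signal > 0, fs_position > 0)
  if (fs_position > fs_signal)
    stop_betasleep("fs_position must not exceed fs_signal",
                   "betasleep_format_error")
  required <- c("frontal_eeg", "hippocampus_lfp", "emg")
  missing_ch <- setdiff(required, names(channels))
  if (length(missing_ch))
    stop_betasleep(paste0("missing channel(s): ",
                          paste(missing_ch, collapse = ", ")),
                   "betasleep_missing_channel")
  n_expected <- round(duration_s * fs_signal)
  lens <- vapply(channels, length, integer(1))
  if (any(lens != n_expected))
    stop_betasleep(sprintf(
      "all signal channels must have length round(duration_s * fs_signal) = %d",
      n_expected), "betasleep_format_error")
  if (!is.null(position)) {
    position <- as.matrix(position)
    if (ncol(position) != 2L)
      stop_betasleep("position must have two columns (x, y)",
                     "betasleep_format_error")
    colnames(position) <- c("x", "y")
  }
  structure(list(mouse_id = mouse_id, genotype = genotype,
                 age_weeks = age_weeks, channels = channels,
                 fs_signal = fs_signal, position = position,
                 fs_position = fs_position, duration_s = duration_s),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s (%s, %.3g wk): %.4g s @ %g Hz, %d channels\n",
              x$mouse_id, x$genotype, x$age_weeks, x$duration_s, x$fs_signal,
              length(x$channels)))
  invisible(x)
}

#' Hypnogram: per-epoch vigilance-state labels
#'
#' Sequence of vigilance-state labels on a uniform epoch grid. Epoch `i`
#' covers the half-open interval
#' `[start_time_s + (i-1)*epoch_len_s, start_time_s + i*epoch_len_s)`.
#' The default 2-s epoch equals the spectrogram hop, so a hypnogram produced
#' by the scorer is aligned one-to-one with spectrogram windows (whose
#' centers sit at the epoch midpoints).
#'
#' @param labels Character vector over [VIGILANCE_STATES]; non-empty.
#' @param epoch_len_s Epoch length in seconds (> 0); default 2.
#' @param start_time_s Start of the first epoch in seconds from session start.
#'
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len_s = 2, start_time_s = 0) {
  labels <- as.character(labels)
  if (!length(labels))
    stop_betasleep("labels must be non-empty", "betasleep_format_error")
  bad <- setdiff(unique(labels), VIGILANCE_STATES)
  if (length(bad))
    stop_betasleep(paste0("unknown state label(s): ",
                          paste(bad, collapse = ", ")),
                   "betasleep_format_error")
  stopifnot(epoch_len_s > 0)
  structure(list(labels = labels, epoch_len_s = epoch_len_s,
                 start_time_s = start_time_s),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = VIGILANCE_STATES))
  cat(sprintf("<hypnogram> %d epochs x %g s from t = %g s\n",
              length(x$labels), x$epoch_len_s, x$start_time_s))
  print(tab)
  invisible(x)
}

# Epoch index for each time point; NA outside the labelled range.
hypnogram_index <- function(hyp, times) {
  idx <- floor((times - hyp$start_time_s) / hyp$epoch_len_s) + 1
  idx[idx < 1 | idx > length(hyp$labels)] <- NA_integer_
  as.integer(idx)
}

# State label at each time point (NA outside range).
hypnogram_state_at <- function(hyp, times) {
  idx <- hypnogram_index(hyp, times)
  out <- rep(NA_character_, length(times))
  ok <- !is.na(idx)
  out[ok] <- hyp$labels[idx[ok]]
  out
}

#' Longitudinal hindlimb-clasping record
#'
#' Monthly tail-suspension observations for one mouse: at each recording age,
#' whether hindlimb clasping was observed.
#'
#' @param mouse_id Character scalar.
#' @param age_weeks Numeric vector of observation ages, strictly increasing.
#' @param clasp_observed Logical vector, same length as `age_weeks`.
#'
#' @return A data frame with columns `mouse_id`, `age_weeks`, `clasp`.
#' @export
clasping_record <- function(mouse_id, age_weeks, clasp_observed) {
  stopifnot(length(age_weeks) == length(clasp_observed))
  if (length(age_weeks) > 1 && any(diff(age_weeks) <= 0))
    stop_betasleep("observation ages must be strictly increasing",
                   "betasleep_format_error")
  data.frame(mouse_id = mouse_id, age_weeks = as.numeric(age_weeks),
             clasp = as.logical(clasp_observed))
}

#' Write / read a hypnogram as CSV
#'
#' The CSV has columns `start_s` (epoch start time) and `state`.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @param comments Optional character vector of `#` header comment lines.
#' @return `read_hypnogram_csv` returns a [hypnogram()].
#' @export
write_hypnogram_csv <- function(hyp, path, comments = character()) {
  starts <- hyp$start_time_s + (seq_along(hyp$labels) - 1) * hyp$epoch_len_s
  write_csv_commented(data.frame(start_s = starts, state = hyp$labels),
                      path, comments)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- read_csv_commented(path)
  if (!all(c("start_s", "state") %in% names(df)))
    stop_betasleep("hypnogram CSV needs columns start_s,state",
                   "betasleep_format_error")
  len <- if (nrow(df) > 1) df$start_s[2] - df$start_s[1] else 2
  hypnogram(df$state, epoch_len_s = len, start_time_s = df$start_s[1])
}
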