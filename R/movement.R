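#' Instantaneous locomotion speed from the position track
#'
#' Converts a video-tracked (x, y) trajectory into a smoothed speed trace:
#' `speed[i]` is the Euclidean step distance between consecutive samples
#' times `fs_position`, with the first value duplicated so the output has
#' the same length as the input, then smoothed by a centered 1-s moving
#' average (window of `fs_position` samples; shrinking at the edges). The
#' 1-s window suppresses tracker jitter while still resolving behavioral
#' arrests of a few seconds.
#'
#' @param position Two-column numeric matrix or data frame of (x, y)
#'   coordinates in cm; at least 2 rows.
#' @param fs_position Position sampling rate in Hz (default 50).
#'
#' @return Numeric vector of speeds in cm/s, same length as the track.
#' @export
compute_movement <- function(position, fs_position = 50) {
  position <- as.matrix(position)
  if (nrow(position) < 2L)
    stop_betasleep("need at least 2 position samples",
                   "betasleep_input_size_error")
  step <- sqrt(diff(position[, 1])^2 + diff(position[, 2])^2)
  speed <- c(step[1], step) * fs_position
  moving_average(speed, round(fs_position))
}
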