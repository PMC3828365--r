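#' Thresholds for automated vigilance-state scoring
#'
#' The scorer implements the classical criteria — active waking by camera
#' movement; REM by low EMG, immobility and strong theta; SWS by wide-band
#' 2-8 Hz activity, immobility and low EMG; quiet waking otherwise — as a
#' fixed decision cascade with config-exposed thresholds. The theta/delta
#' ratio uses non-overlapping bands (theta 5-9 Hz over delta 2-4 Hz) so that
#' a strong theta rhythm, which itself lies inside 2-8 Hz, can drive the
#' ratio well above one.
#'
#' @param speed_active Epoch mean speed (cm/s) above which an epoch is
#'   active waking (default 2).
#' @param speed_still Epoch mean speed below which the animal counts as
#'   immobile (tracker noise floor; default 0.5).
#' @param emg_low EMG RMS (uV) at or below which muscle tone counts as low
#'   (sleep); default 8.
#' @param emg_light EMG RMS ceiling for "light" muscle tone in quiet waking
#'   (kept for reporting; the cascade classifies quiet waking as the
#'   remainder). Must exceed `emg_low`.
#' @param theta_ratio_rem Theta/delta power ratio at or above which an
#'   immobile low-EMG epoch is REM (default 2).
#' @param broadband_sws Minimum fraction of 2-8 Hz power in the 0.5-100 Hz
#'   total for an immobile low-EMG epoch to be SWS (default 0.45).
#' @param smoothing_epochs Odd width of the majority filter applied to the
#'   label sequence (default 3).
#' @param theta_band,delta_band,broadband_band,total_band Frequency bands
#'   (Hz) used by the features.
#'
#' @return An object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(speed_active = 2, speed_still = 0.5,
                               emg_low = 8, emg_light = 20,
                               theta_ratio_rem = 2, broadband_sws = 0.45,
                               smoothing_epochs = 3,
                               theta_band = c(5, 9), delta_band = c(2, 4),
                               broadband_band = c(2, 8),
                               total_band = c(0.5, 100)) {
  if (emg_low >= emg_light)
    stop_betasleep("emg_low must be < emg_light", "betasleep_config_error")
  if (any(c(speed_active, emg_low, emg_light, theta_ratio_rem,
            broadband_sws) <= 0))
    stop_betasleep("thresholds must be > 0", "betasleep_config_error")
  smoothing_epochs <- as.integer(smoothing_epochs)
  if (smoothing_epochs < 1L || smoothing_epochs %% 2L == 0L)
    stop_betasleep("smoothing_epochs must be a positive odd integer",
                   "betasleep_config_error")
  structure(list(speed_active = speed_active, speed_still = speed_still,
                 emg_low = emg_low, emg_light = emg_light,
                 theta_ratio_rem = theta_ratio_rem,
                 broadband_sws = broadband_sws,
                 smoothing_epochs = smoothing_epochs,
                 theta_band = theta_band, delta_band = delta_band,
                 broadband_band = broadband_band, total_band = total_band),
            class = "scoring_thresholds")
}

# Majority filter over a centered window of k labels; the center label is
# kept whenever it ties for the majority, so smoothing can never introduce a
# state absent from the window.
majority_filter <- function(labels, k) {
  k <- as.integer(k)
  if (k <= 1L) return(labels)
  n <- length(labels)
  half <- (k - 1L) %/% 2L
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    win <- labels[lo:hi]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (labels[i] %in% top) labels[i] else
      win[match(TRUE, win %in% top)]
  }
  out
}

#' Per-epoch EMG RMS
#'
#' RMS computed in 0.5-s sub-windows and averaged within each 2-s epoch of
#' the analysis grid (epochs centered on the spectrogram window centers).
#'
#' @param emg EMG trace in uV.
#' @param fs Sampling rate, Hz.
#' @param n_epochs Number of epochs (= spectrogram windows).
#' @param epoch_len_s,start_time_s Epoch grid (defaults 2 s starting at 1 s).
#' @param subwin_s RMS sub-window length, seconds (default 0.5).
#'
#' @return Numeric vector of length `n_epochs`, uV.
#' @export
epoch_emg_rms <- function(emg, fs, n_epochs, epoch_len_s = 2,
                          start_time_s = 1, subwin_s = 0.5) {
  nsub <- round(subwin_s * fs)
  vapply(seq_len(n_epochs), function(i) {
    t0 <- start_time_s + (i - 1) * epoch_len_s
    i0 <- max(1L, round(t0 * fs) + 1L)
    i1 <- min(length(emg), round((t0 + epoch_len_s) * fs))
    x <- emg[i0:i1]
    nw <- max(1L, length(x) %/% nsub)
    mean(vapply(seq_len(nw), function(j) {
      sqrt(mean(x[((j - 1) * nsub + 1):min(j * nsub, length(x))]^2))
    }, numeric(1)))
  }, numeric(1))
}

#' Per-epoch mean speed
#'
#' Mean of the smoothed speed trace within each epoch of the analysis grid.
#'
#' @param speed Speed trace from [compute_movement()], cm/s.
#' @param fs_position Position sampling rate, Hz.
#' @inheritParams epoch_emg_rms
#' @return Numeric vector of length `n_epochs`, cm/s.
#' @export
epoch_speed <- function(speed, fs_position, n_epochs, epoch_len_s = 2,
                        start_time_s = 1) {
  vapply(seq_len(n_epochs), function(i) {
    t0 <- start_time_s + (i - 1) * epoch_len_s
    i0 <- max(1L, round(t0 * fs_position) + 1L)
    i1 <- min(length(speed), round((t0 + epoch_len_s) * fs_position))
    mean(speed[i0:i1])
  }, numeric(1))
}

#' Score vigilance states epoch by epoch
#'
#' Decision cascade per epoch: (1) moving (`speed > speed_active`) gives
#' active waking; (2) otherwise, immobile with low EMG and a theta/delta
#' ratio at or above `theta_ratio_rem` gives REM; (3) otherwise, immobile
#' with low EMG and a 2-8 Hz power fraction at or above `broadband_sws`
#' gives SWS; (4) everything else is quiet waking. The label sequence is
#' then majority-filtered over `smoothing_epochs` epochs.
#'
#' @param spg_hippocampus Hippocampal [compute_spectrogram()] (theta/delta
#'   and wide-band features are computed from it).
#' @param emg_rms Per-epoch EMG RMS (uV), aligned with the spectrogram
#'   windows ([epoch_emg_rms()]).
#' @param speed Per-epoch mean speed (cm/s), aligned ([epoch_speed()]).
#' @param thresholds A [scoring_thresholds()].
#'
#' @return A [hypnogram()] on the spectrogram window grid.
#' @export
score_states <- function(spg_hippocampus, emg_rms, speed,
                         thresholds = scoring_thresholds()) {
  n <- nrow(spg_hippocampus$power)
  if (length(emg_rms) != n || length(speed) != n)
    stop_betasleep("emg_rms and speed must have one value per window",
                   "betasleep_alignment_error")
  thr <- thresholds
  f <- spg_hippocampus$freqs
  P <- spg_hippocampus$power
  pow_band <- function(band) rowSums(P[, band_mask(f, band), drop = FALSE])
  theta <- pow_band(thr$theta_band)
  delta <- pow_band(thr$delta_band)
  ratio <- theta / pmax(delta, .Machine$double.xmin)
  bbfrac <- pow_band(thr$broadband_band) /
    pmax(pow_band(thr$total_band), .Machine$double.xmin)

  still <- speed < thr$speed_still
  lab <- rep("QUIET_WAKE", n)
  lab[speed > thr$speed_active] <- "ACTIVE_WAKE"
  rem <- speed <= thr$speed_active & still & emg_rms <= thr$emg_low &
    ratio >= thr$theta_ratio_rem
  sws <- speed <= thr$speed_active & still & emg_rms <= thr$emg_low &
    !rem & bbfrac >= thr$broadband_sws
  lab[rem] <- "REM"
  lab[sws] <- "SWS"
  lab <- majority_filter(lab, thr$smoothing_epochs)
  hypnogram(lab, epoch_len_s = spg_hippocampus$hop_s,
            start_time_s = spg_hippocampus$window_times[1] -
              spg_hippocampus$hop_s / 2)
}

#' Agreement between a predicted and a ground-truth hypnogram
#'
#' @param predicted,truth [hypnogram()]s on identical epoch grids.
#' @return An object of class `scoring_accuracy`: `confusion` (truth rows x
#'   predicted columns), `overall` fraction correct, `recall` and
#'   `precision` per state.
#' @export
scoring_accuracy <- function(predicted, truth) {
  if (length(predicted$labels) != length(truth$labels) ||
      !isTRUE(all.equal(predicted$epoch_len_s, truth$epoch_len_s)) ||
      !isTRUE(all.equal(predicted$start_time_s, truth$start_time_s)))
    stop_betasleep("hypnograms must share the same epoch grid",
                   "betasleep_alignment_error")
  lev <- VIGILANCE_STATES
  confusion <- table(truth = factor(truth$labels, lev),
                     predicted = factor(predicted$labels, lev))
  overall <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  structure(list(confusion = confusion, overall = overall,
                 recall = recall, precision = precision),
            class = "scoring_accuracy")
}

#' @export
print.scoring_accuracy <- function(x, ...) {
  cat(sprintf("<scoring_accuracy> overall %.3f\n", x$overall))
  print(x$confusion)
  invisible(x)
}
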