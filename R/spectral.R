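#' Canonical frequency bands
#'
#' Named frequency bands (Hz) used throughout the analysis: `beta_sum`
#' (15-40 Hz, the summation band for beta power), `beta_display` (20-35 Hz,
#' the descriptive band in which the burst rhythm is most visible),
#' `theta_sum` (4-8 Hz), `theta_peak` (4-9 Hz, the search band for the
#' theta peak), `delta_comod` (2-5 Hz, the hippocampal delta band of the
#' waking comodulogram) and `normalization` (0.5-100 Hz, the range over
#' which normalized spectra sum to one).
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
spectral_bands <- function() {
  list(beta_sum = c(15, 40), beta_display = c(20, 35),
       theta_sum = c(4, 8), theta_peak = c(4, 9),
       delta_comod = c(2, 5), normalization = c(0.5, 100))
}

#' Spectrogram with Gaussian taper
#'
#' Sliding-window power spectral density: FFTs on 4-s windows with 50 %
#' overlap (2-s hop), each tapered by a Gaussian with `sigma =` window
#' length / 6 (so the window is close to compactly supported at +-3 sigma).
#' Power is one-sided and scaled so that Parseval holds for the tapered
#' window: `P = 2 |X|^2 / (fs * sum(w^2))` (half that at DC and Nyquist).
#' With a 4-s window the frequency resolution is 0.25 Hz.
#'
#' @param trace Numeric signal vector (microvolts).
#' @param fs Sampling rate in Hz.
#' @param window_len_s Window length in seconds (default 4).
#' @param hop_s Hop between window starts in seconds (default 2).
#'
#' @return An object of class `spectrogram`: list with `power`
#'   (`n_windows x n_freq` matrix, uV^2/Hz), `freqs` (Hz), `window_times`
#'   (window center times, s), `fs`, `window_len_s`, `hop_s`.
#' @export
compute_spectrogram <- function(trace, fs, window_len_s = 4, hop_s = 2) {
  L <- round(window_len_s * fs)
  hop <- round(hop_s * fs)
  if (length(trace) < L)
    stop_betasleep("trace shorter than one analysis window",
                   "betasleep_input_size_error")
  n_win <- floor((length(trace) - L) / hop) + 1
  starts <- (seq_len(n_win) - 1L) * hop
  w <- exp(-0.5 * (((seq_len(L) - 1) - (L - 1) / 2) / (L / 6))^2)
  seg <- matrix(trace[outer(seq_len(L), starts, `+`)], nrow = L)
  X <- mvfft(seg * w)
  n_freq <- floor(L / 2) + 1L
  P <- (Mod(X[seq_len(n_freq), , drop = FALSE])^2) * (2 / (fs * sum(w^2)))
  P[1, ] <- P[1, ] / 2
  if (L %% 2 == 0) P[n_freq, ] <- P[n_freq, ] / 2
  structure(list(power = t(P),
                 freqs = (seq_len(n_freq) - 1) * fs / L,
                 window_times = starts / fs + window_len_s / 2,
                 fs = fs, window_len_s = window_len_s, hop_s = hop_s),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows x %d bins (%g-%g Hz, %.3g Hz bins)\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$freqs, b$freqs)) &&
    isTRUE(all.equal(a$window_times, b$window_times))
}

# Indices of spectrogram windows whose center time falls in an epoch of one
# of the given states.
windows_in_state <- function(spg, hyp, states) {
  lab <- hypnogram_state_at(hyp, spg$window_times)
  which(!is.na(lab) & lab %in% states)
}

#' State-conditioned normalized power spectrum
#'
#' Averages the spectrogram windows whose center time falls in an epoch of
#' the given vigilance state, then normalizes the averaged spectrum by its
#' sum over `normalization_range` (default 0.5-100 Hz), so spectra are
#' comparable across probes and animals.
#'
#' @param spg A [compute_spectrogram()] result.
#' @param hyp A [hypnogram()].
#' @param state A state label, or a vector of labels to pool (e.g.
#'   [WAKE_STATES]).
#' @param normalization_range `c(lo, hi)` Hz over which the spectrum sums
#'   to one.
#'
#' @return An object of class `psd_spectrum`: `values` (normalized,
#'   unitless), `freqs`, `state`, `n_windows`, `normalization_range`.
#' @export
state_spectrum <- function(spg, hyp, state,
                           normalization_range = spectral_bands()$normalization) {
  sel <- windows_in_state(spg, hyp, state)
  if (!length(sel))
    stop_betasleep(sprintf("no spectrogram window in state %s",
                           paste(state, collapse = "+")),
                   "betasleep_empty_state_error")
  v <- colMeans(spg$power[sel, , drop = FALSE])
  m <- band_mask(spg$freqs, normalization_range)
  total <- sum(v[m])
  if (total <= 0)
    v <- v * 0
  else
    v <- v / total
  structure(list(values = v, freqs = spg$freqs,
                 state = paste(state, collapse = "+"),
                 n_windows = length(sel),
                 normalization_range = normalization_range),
            class = "psd_spectrum")
}

#' @export
print.psd_spectrum <- function(x, ...) {
  cat(sprintf("<psd_spectrum> state %s, %d windows, %d bins\n",
              x$state, x$n_windows, length(x$freqs)))
  invisible(x)
}

#' Summed band power of a normalized spectrum
#'
#' Sum of the normalized power values for bins with `lo <= f <= hi`
#' (inclusive edges). Because spectra are normalized, the result is the
#' fraction of total (0.5-100 Hz) power in the band.
#'
#' @param spec A [state_spectrum()] result.
#' @param lo,hi Band edges in Hz, `lo < hi`, inside the frequency axis.
#'
#' @return Unitless summed power.
#' @export
band_power <- function(spec, lo, hi) {
  check_band(c(lo, hi), spec$freqs, "band")
  sum(spec$values[band_mask(spec$freqs, c(lo, hi))])
}

#' Peak location within a band
#'
#' Frequency and normalized power of the maximum within `[lo, hi]`; ties are
#' broken toward the lowest frequency.
#'
#' @inheritParams band_power
#' @return List with `peak_freq` (Hz) and `peak_power`.
#' @export
peak_in_band <- function(spec, lo, hi) {
  check_band(c(lo, hi), spec$freqs, "band")
  m <- which(band_mask(spec$freqs, c(lo, hi)))
  i <- m[which.max(spec$values[m])]
  list(peak_freq = spec$freqs[i], peak_power = spec$values[i])
}

#' Detect a beta peak over the 1/f background
#'
#' Fits a straight line to log10(power) versus log10(frequency) over the
#' 10-55 Hz range *excluding* the 15-40 Hz beta band, i.e. the aperiodic
#' 1/f background flanking the band. A beta peak is declared present when
#' the ratio of observed power to the fitted background reaches the
#' prominence threshold (default 2.0) at a local maximum inside 15-40 Hz.
#' The spectrum is lightly smoothed beforehand (centered moving average of
#' `smooth_bins` bins, default 5 = 1.25 Hz): the single-bin variance of a
#' tapered periodogram averaged over a few dozen windows is otherwise large
#' enough to clear the threshold by chance, while genuine burst peaks are
#' several hertz wide and pass through the smoothing unchanged.
#'
#' @param spec A [state_spectrum()] result whose frequency axis covers
#'   10-55 Hz.
#' @param band Beta search band, default `c(15, 40)` Hz.
#' @param fit_range Background fitting range, default `c(10, 55)` Hz.
#' @param threshold Prominence ratio required for presence (default 2).
#' @param smooth_bins Width (bins) of the pre-detection moving average;
#'   1 disables smoothing.
#'
#' @return An object of class `beta_peak`: `present` (logical), `peak_freq`
#'   (Hz, `NA` if no candidate), `peak_power` (normalized units),
#'   `prominence` (max ratio over fitted background at a local maximum).
#' @export
detect_beta_peak <- function(spec, band = spectral_bands()$beta_sum,
                             fit_range = c(10, 55), threshold = 2,
                             smooth_bins = 5) {
  f <- spec$freqs
  if (min(f) > fit_range[1] || max(f) < fit_range[2])
    stop_betasleep("frequency axis must cover the 10-55 Hz fitting range",
                   "betasleep_range_error")
  in_fit <- band_mask(f, fit_range) & !band_mask(f, band) & f > 0
  v <- moving_average(spec$values, smooth_bins)
  ok <- in_fit & v > 0
  fit <- lm(log10(v[ok]) ~ log10(f[ok]))
  cf <- stats::coef(fit)
  in_band <- which(band_mask(f, band) & f > 0)
  bg <- 10^(cf[1] + cf[2] * log10(f[in_band]))
  ratio <- v[in_band] / bg
  k <- length(ratio)
  result <- structure(list(present = FALSE, peak_freq = NA_real_,
                           peak_power = NA_real_, prominence = max(ratio)),
                      class = "beta_peak")
  if (k < 3) return(result)
  is_locmax <- c(FALSE, ratio[2:(k - 1)] > ratio[1:(k - 2)] &
                   ratio[2:(k - 1)] >= ratio[3:k], FALSE)
  if (!any(is_locmax)) return(result)
  cand <- which(is_locmax)
  best <- cand[which.max(ratio[cand])]
  result$peak_freq <- f[in_band][best]
  result$peak_power <- v[in_band][best]
  result$prominence <- ratio[best]
  result$present <- ratio[best] >= threshold
  result
}

#' @export
print.beta_peak <- function(x, ...) {
  if (x$present)
    cat(sprintf("<beta_peak> present at %.2f Hz (prominence %.2f)\n",
                x$peak_freq, x$prominence))
  else
    cat(sprintf("<beta_peak> absent (max prominence %.2f)\n", x$prominence))
  invisible(x)
}

#' Export a spectrum (or several) as CSV
#'
#' One `freq_hz` column plus one column per spectrum.
#'
#' @param specs A single [state_spectrum()] result or a named list of them.
#' @param path Output CSV path.
#' @param comments Optional `#` header comment lines.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(specs, path, comments = character()) {
  if (inherits(specs, "psd_spectrum")) specs <- list(spectrum = specs)
  df <- data.frame(freq_hz = specs[[1]]$freqs)
  for (nm in names(specs)) df[[nm]] <- specs[[nm]]$values
  write_csv_commented(df, path, comments)
}
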