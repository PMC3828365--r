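#' Cross-channel power-power comodulogram
#'
#' For each pair of frequency bins (fA of channel A, fB of channel B),
#' the Pearson correlation between the two per-window power time series,
#' restricted to spectrogram windows whose epoch is in the given state(s).
#' Power is log10-transformed by default, which stabilizes its heavy-tailed
#' distribution; set `log_power = FALSE` for raw power. Two-sided p-values
#' come from the t transform of r with n - 2 degrees of freedom (reported
#' uncorrected for multiple comparisons).
#'
#' @param spg_a,spg_b [compute_spectrogram()] results on identical window
#'   grids (channel A on rows of `r`, channel B on columns).
#' @param hyp A [hypnogram()].
#' @param states State label(s) defining the analysis windows (e.g.
#'   [WAKE_STATES] for the waking-state comodulogram).
#' @param freq_range `c(lo, hi)` Hz; bins outside are dropped to bound the
#'   matrix size (default 1-55 Hz).
#' @param log_power Correlate log10 power (default) or raw power.
#'
#' @return An object of class `comodulogram`: `r` and `p` matrices
#'   (`freqs_a x freqs_b`), `freqs_a`, `freqs_b`, `state`, `n_windows`.
#' @export
compute_comodulogram <- function(spg_a, spg_b, hyp, states = WAKE_STATES,
                                 freq_range = c(1, 55), log_power = TRUE) {
  if (!same_grid(spg_a, spg_b))
    stop_betasleep("spectrograms must share the same window and frequency grid",
                   "betasleep_alignment_error")
  sel <- windows_in_state(spg_a, hyp, states)
  if (length(sel) < 10)
    stop_betasleep(sprintf(
      "need >= 10 windows in state %s, found %d",
      paste(states, collapse = "+"), length(sel)),
      "betasleep_insufficient_data_error")
  ka <- band_mask(spg_a$freqs, freq_range)
  kb <- band_mask(spg_b$freqs, freq_range)
  ma <- spg_a$power[sel, ka, drop = FALSE]
  mb <- spg_b$power[sel, kb, drop = FALSE]
  if (log_power) {
    floor_val <- .Machine$double.xmin
    ma <- log10(pmax(ma, floor_val))
    mb <- log10(pmax(mb, floor_val))
  }
  n <- length(sel)
  r <- suppressWarnings(cor(ma, mb))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  structure(list(r = r, p = p,
                 freqs_a = spg_a$freqs[ka], freqs_b = spg_b$freqs[kb],
                 state = paste(states, collapse = "+"), n_windows = n),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d x %d bins, state %s, %d windows, r in [%.3f, %.3f]\n",
              nrow(x$r), ncol(x$r), x$state, x$n_windows,
              min(x$r), max(x$r)))
  invisible(x)
}

#' Extremal correlation within a band pair
#'
#' Location and value of the maximal (or minimal) correlation coefficient in
#' the sub-matrix `band_a x band_b`; ties are broken toward the lowest
#' `(fA, fB)` pair.
#'
#' @param com A [compute_comodulogram()] result.
#' @param band_a,band_b `c(lo, hi)` Hz intervals for channel A (rows) and
#'   channel B (columns).
#' @param mode `"max"` or `"min"`.
#'
#' @return List with `freq_a`, `freq_b` (Hz), `r` and `p`.
#' @export
band_extrema <- function(com, band_a, band_b, mode = c("max", "min")) {
  mode <- match.arg(mode)
  check_band(band_a, com$freqs_a, "band_a")
  check_band(band_b, com$freqs_b, "band_b")
  ia <- which(band_mask(com$freqs_a, band_a))
  ib <- which(band_mask(com$freqs_b, band_b))
  sub <- com$r[ia, ib, drop = FALSE]
  ext <- if (mode == "max") max(sub) else min(sub)
  hits <- which(sub == ext, arr.ind = TRUE)
  # lexicographic tie-break on (fA, fB)
  ord <- order(hits[, 1], hits[, 2])
  hit <- hits[ord[1], ]
  list(freq_a = com$freqs_a[ia[hit[1]]],
       freq_b = com$freqs_b[ib[hit[2]]],
       r = ext,
       p = com$p[ia[hit[1]], ib[hit[2]]])
}

#' Export a comodulogram as CSV
#'
#' Matrix layout: first column `freq_a_hz`, remaining columns one per
#' channel-B frequency (header `fB_<Hz>`).
#'
#' @param com A [compute_comodulogram()] result.
#' @param path Output CSV path.
#' @param comments Optional `#` header comment lines.
#' @return `path`, invisibly.
#' @export
write_comodulogram_csv <- function(com, path, comments = character()) {
  df <- data.frame(freq_a_hz = com$freqs_a)
  m <- as.data.frame(com$r)
  names(m) <- sprintf("fB_%g", com$freqs_b)
  write_csv_commented(cbind(df, m), path, comments)
}
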