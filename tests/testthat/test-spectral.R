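test_that("spectrogram geometry and degenerate inputs behave as specified", {
  fs <- 200
  spg <- compute_spectrogram(numeric(60 * fs), fs)
  expect_equal(nrow(spg$power), 29)            # floor((60-4)/2)+1
  expect_true(all(spg$power == 0))
  expect_equal(spg$freqs[2] - spg$freqs[1], 0.25)
  expect_equal(range(spg$freqs), c(0, fs / 2))

  one <- compute_spectrogram(sin(2 * pi * 5 * (0:(4 * fs - 1)) / fs), fs)
  expect_equal(nrow(one$power), 1)
  expect_error(compute_spectrogram(numeric(4 * fs - 1), fs),
               class = "betasleep_input_size_error")
})

test_that("a pure tone peaks at its own frequency in every window", {
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  spg <- compute_spectrogram(sin(2 * pi * 25 * t), fs)
  peaks <- spg$freqs[apply(spg$power, 1, which.max)]
  expect_true(all(peaks == 25))
})

test_that("spectrogram equals a brute-force windowed DFT", {
  fs <- 200
  withr::with_seed(8, trace <- rnorm(10 * fs))
  spg <- compute_spectrogram(trace, fs)
  L <- 4 * fs
  w <- exp(-0.5 * (((seq_len(L) - 1) - (L - 1) / 2) / (L / 6))^2)
  u <- sum(w^2)
  for (win in seq_len(nrow(spg$power))) {
    seg <- trace[(win - 1) * 2 * fs + seq_len(L)] * w
    # direct DFT, no FFT
    ks <- 0:(L / 2)
    ref <- vapply(ks, function(k) {
      z <- sum(seg * exp(-2i * pi * k * (seq_len(L) - 1) / L))
      Mod(z)^2 * 2 / (fs * u)
    }, numeric(1))
    ref[1] <- ref[1] / 2
    ref[length(ref)] <- ref[length(ref)] / 2
    expect_lt(max(abs(spg$power[win, ] - ref)) / max(ref), 1e-8)
  }
})

test_that("state spectra select the right windows and normalize to one", {
  # constant spectrogram: the state spectrum is the common row, normalized
  freqs <- seq(0, 120, by = 0.25)
  row <- freqs + 1
  spg <- make_spectrogram(matrix(row, 20, length(freqs), byrow = TRUE), freqs)
  hyp <- hypnogram(rep("SWS", 20), 2, 1)
  sp <- state_spectrum(spg, hyp, "SWS")
  m <- freqs >= 0.5 & freqs <= 100
  expect_equal(sum(sp$values[m]), 1, tolerance = 1e-12)
  expect_equal(sp$values, row / sum(row[m]), ignore_attr = TRUE)
  expect_error(state_spectrum(spg, hyp, "REM"),
               class = "betasleep_empty_state_error")

  # distinct tones per state appear only in their own state's spectrum
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  trace <- ifelse(t < 30, sin(2 * pi * 10 * t), sin(2 * pi * 30 * t))
  spg2 <- compute_spectrogram(trace, fs)
  lab <- ifelse(spg2$window_times < 29, "SWS",
                ifelse(spg2$window_times > 31, "REM", "QUIET_WAKE"))
  hyp2 <- hypnogram(lab, 2, 1)
  s_sws <- state_spectrum(spg2, hyp2, "SWS")
  s_rem <- state_spectrum(spg2, hyp2, "REM")
  expect_equal(peak_in_band(s_sws, 1, 99)$peak_freq, 10)
  expect_equal(peak_in_band(s_rem, 1, 99)$peak_freq, 30)
  expect_lt(band_power(s_sws, 25, 35) / band_power(s_sws, 5, 15), 1e-3)
  expect_lt(band_power(s_rem, 5, 15) / band_power(s_rem, 25, 35), 1e-3)
})

test_that("normalized spectra sum to one over the range for random inputs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      freqs <- seq(0, 100, by = 0.25)
      p <- matrix(rexp(30 * length(freqs)), 30)
    })
    spg <- make_spectrogram(p, freqs)
    hyp <- hypnogram(rep("REM", 30), 2, 1)
    sp <- state_spectrum(spg, hyp, "REM")
    expect_equal(sum(sp$values[freqs >= 0.5 & freqs <= 100]), 1,
                 tolerance = 1e-9)
    expect_true(all(sp$values >= 0))
  }
})

test_that("band power sums inclusive bins of the normalized spectrum", {
  freqs <- seq(0, 120, by = 0.25)
  flat <- make_spectrum(rep(1, length(freqs)), freqs)
  # 101 bins in 15-40 out of 399 in 0.5-100
  expect_equal(band_power(flat, 15, 40), 101 / 399, tolerance = 1e-12)
  expect_equal(band_power(flat, 0.5, 100), 1, tolerance = 1e-12)

  conc <- make_spectrum(as.numeric(freqs == 25), freqs)
  expect_equal(band_power(conc, 15, 40), 1)
  expect_error(band_power(flat, 130, 150), class = "betasleep_range_error")
  expect_error(band_power(flat, 40, 15), class = "betasleep_range_error")
})

test_that("peak location honors amplitude and low-frequency tie-breaks", {
  freqs <- seq(0, 120, by = 0.25)
  v <- rep(0.01, length(freqs))
  v[freqs == 7.5] <- 1
  expect_equal(peak_in_band(make_spectrum(v, freqs), 4, 9)$peak_freq, 7.5)

  v2 <- rep(0.01, length(freqs))
  v2[freqs == 20] <- 2; v2[freqs == 30] <- 1
  expect_equal(peak_in_band(make_spectrum(v2, freqs), 15, 40)$peak_freq, 20)

  v3 <- rep(0.01, length(freqs))
  v3[freqs == 22] <- 1; v3[freqs == 28] <- 1    # tie: lowest wins
  expect_equal(peak_in_band(make_spectrum(v3, freqs), 15, 40)$peak_freq, 22)
})

test_that("beta detection separates bumps from the 1/f background", {
  freqs <- seq(0, 120, by = 0.25)
  f <- pmax(freqs, 0.5)
  bg <- f^-2

  none <- detect_beta_peak(make_spectrum(bg, freqs))
  expect_false(none$present)

  bump <- function(gain) bg * (1 + (gain - 1) * exp(-(freqs - 25)^2 / 8))
  hit <- detect_beta_peak(make_spectrum(bump(5), freqs))
  expect_true(hit$present)
  expect_lt(abs(hit$peak_freq - 25), 0.26)
  expect_gt(hit$prominence, 2)

  weak <- detect_beta_peak(make_spectrum(bump(1.5), freqs))
  expect_false(weak$present)
  expect_lt(weak$prominence, 2)

  short <- make_spectrum(rep(1, 81), seq(0, 20, by = 0.25),
                         normalization_range = c(0.5, 20))
  expect_error(detect_beta_peak(short), class = "betasleep_range_error")
})
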