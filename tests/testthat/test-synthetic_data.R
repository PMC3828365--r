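test_that("configuration invariants are enforced", {
  expect_error(generator_config("WT", beta_rate_per_min =
                                  stats::setNames(c(0, 0, 0, 1),
                                                  VIGILANCE_STATES)),
               class = "betasleep_config_error")
  # transgenic rates must increase from active waking toward REM
  expect_error(generator_config("R6/1", beta_rate_per_min =
                                  stats::setNames(c(9, 8, 12, 15),
                                                  VIGILANCE_STATES)),
               class = "betasleep_config_error")
  expect_error(generator_config("R6/1", nonsense = 1),
               class = "betasleep_config_error")
  # age model anchors: center frequency 25 Hz at the default symptomatic age,
  # amplitude tripling across the age range
  cfg <- generator_config("R6/1")
  expect_equal(betasleep:::beta_center_freq(cfg, 17.5), 25)
  expect_equal(betasleep:::beta_amp_uv(cfg, 26) /
                 betasleep:::beta_amp_uv(cfg, 9), 3)
})

test_that("an absorbing state yields a constant hypnogram", {
  cfg <- generator_config("WT")
  tr <- cfg$transitions * 0
  tr["SWS", "SWS"] <- 1
  tr["ACTIVE_WAKE", "QUIET_WAKE"] <- 1
  tr["QUIET_WAKE", "SWS"] <- 1
  tr["REM", "SWS"] <- 1
  cfg$transitions <- tr
  hyp <- simulate_state_sequence(cfg, 120, seed = 1)
  expect_true(all(hyp$labels == "SWS"))
})

test_that("dwell times follow the configured exponential means", {
  cfg <- generator_config("R6/1",
                          dwell_mean_s = stats::setNames(rep(5, 4),
                                                         VIGILANCE_STATES))
  hyp <- simulate_state_sequence(cfg, 320000, seed = 11)
  b <- attr(hyp, "bouts")
  b <- b[-nrow(b), ]                     # last bout is truncated
  dwell <- b$end_s - b$start_s
  counts <- table(b$state)
  expect_true(all(counts >= 10000))
  means <- tapply(dwell, b$state, mean)
  expect_true(all(abs(means - 5) / 5 < 0.05))
})

test_that("REM sleep is entered only from SWS", {
  cfg <- generator_config("R6/1")
  hyp <- simulate_state_sequence(cfg, 50000, seed = 2)
  b <- attr(hyp, "bouts")
  prev <- b$state[-nrow(b)]
  nxt <- b$state[-1]
  expect_gt(sum(nxt == "REM"), 10)
  expect_true(all(prev[nxt == "REM"] == "SWS"))
})

test_that("the generator is reproducible and seed-sensitive", {
  cfg <- generator_config("R6/1", duration_s = 60, fs_signal = 200)
  a <- simulate_session(cfg, seed = 5)
  b <- simulate_session(cfg, seed = 5)
  c <- simulate_session(cfg, seed = 6)
  expect_identical(a$session$channels, b$session$channels)
  expect_identical(a$bursts, b$bursts)
  expect_identical(a$hypnogram$labels, b$hypnogram$labels)
  expect_false(identical(a$session$channels$frontal_eeg,
                         c$session$channels$frontal_eeg))
})

test_that("burst counts match the configured rate and WT has none", {
  # REM-only hypnogram, 5 minutes: expected count = 15/min * 5 = 75
  hyp <- hypnogram(rep("REM", 148), 2, 1)
  cfg <- generator_config("R6/1")
  out <- synthesize_signals(hyp, cfg, seed = 9)
  lambda <- cfg$beta_rate_per_min[["REM"]] * 300 / 60
  expect_lt(abs(nrow(out$bursts) - lambda), 3.5 * sqrt(lambda))
  expect_true(all(out$bursts$state == "REM"))

  wt <- synthesize_signals(hyp, generator_config("WT"), seed = 9)
  expect_equal(nrow(wt$bursts), 0L)
})

test_that("burst amplitude and duration orderings follow the state ordering", {
  cfg <- generator_config("R6/1")
  f <- cfg$beta_amp_factor
  d <- cfg$beta_dur_s
  ord <- c("ACTIVE_WAKE", "QUIET_WAKE", "SWS", "REM")
  expect_true(all(diff(f[ord]) >= 0))
  expect_true(all(diff(d[ord]) >= 0))
  # empirically: mean ground-truth burst duration and amplitude per state
  hyp <- simulate_state_sequence(cfg, 3000, seed = 3)
  out <- synthesize_signals(hyp, cfg, seed = 3)
  bt <- out$bursts
  bt <- bt[bt$state %in% c("QUIET_WAKE", "SWS", "REM"), ]
  mdur <- tapply(bt$end_s - bt$start_s, bt$state, mean)[c("QUIET_WAKE",
                                                          "SWS", "REM")]
  mamp <- tapply(bt$amp_uv, bt$state, mean)[c("QUIET_WAKE", "SWS", "REM")]
  expect_true(all(diff(mdur) > 0))
  expect_true(all(diff(mamp) > 0))
})

test_that("a zero-amplitude configuration produces identically zero channels", {
  zero4 <- stats::setNames(rep(0, 4), VIGILANCE_STATES)
  cfg <- generator_config(
    "WT", duration_s = 30, fs_signal = 200,
    bg_rms_uv = list(hippocampus_lfp = zero4, frontal_eeg = zero4),
    theta_amp_uv = zero4, emg_rms_uv = zero4,
    sws_broadband_rms_uv = c(hippocampus_lfp = 0, frontal_eeg = 0))
  hyp <- simulate_state_sequence(cfg, 30, seed = 1)
  out <- synthesize_signals(hyp, cfg, seed = 1)
  for (ch in out$session$channels) expect_true(all(ch == 0))
})

test_that("too low a sampling rate is rejected", {
  cfg <- generator_config("WT", fs_signal = 100, duration_s = 30)
  hyp <- hypnogram(rep("SWS", 13), 2, 1)
  expect_error(synthesize_signals(hyp, cfg, seed = 1),
               class = "betasleep_config_error")
})

test_that("state-conditioned synthetic spectra peak only at configured oscillations", {
  # oracle periodogram (stats::spec.pgram, an independent estimator) on the
  # hippocampal channel restricted to one state at a time
  cfg <- generator_config("R6/1", duration_s = 300, fs_signal = 200)
  hyp <- hypnogram(rep(c("REM", "SWS"), each = 74), 2, 1)
  out <- synthesize_signals(hyp, cfg, seed = 21)
  x <- out$session$channels$hippocampus_lfp
  fs <- 200
  seg <- function(state) {
    t <- (seq_along(x) - 1) / fs
    lab <- hyp$labels[pmin(pmax(floor((t - 1) / 2) + 1, 1), length(hyp$labels))]
    x[lab == state]
  }
  pg <- function(v) {
    s <- stats::spec.pgram(stats::ts(v, frequency = fs), spans = 15,
                           plot = FALSE, taper = 0.1)
    list(f = s$freq, p = s$spec)
  }
  rem <- pg(seg("REM"))
  sel <- rem$f >= 4 & rem$f <= 12
  expect_lt(abs(rem$f[sel][which.max(rem$p[sel])] - cfg$theta_freq_hz), 0.5)
  sws <- pg(seg("SWS"))
  # SWS power concentrates in the 2-8 Hz wide band, not at theta
  in28 <- sws$f >= 2 & sws$f <= 8
  out28 <- sws$f > 10 & sws$f <= 14
  expect_gt(mean(sws$p[in28]), 5 * mean(sws$p[out28]))
})

test_that("cohort simulation honors the longitudinal design", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(dir, n_r61 = 3, n_wt = 2,
                         session_ages_weeks = c(10, 14),
                         seed = 4,
                         config_overrides = list(duration_s = 30,
                                                 fs_signal = 200))
  expect_equal(nrow(sim$manifest), 10)
  expect_true(all(file.exists(file.path(dir, sim$manifest$path))))
  # clasping lag is exact in ground truth
  expect_equal(sim$onsets$clasp_onset_weeks - sim$onsets$beta_onset_weeks,
               rep(6.67, 3))
  # WT mice never clasp and never have bursts
  wt_ids <- sim$manifest$mouse_id[sim$manifest$genotype == "WT"]
  expect_false(any(sim$clasping$clasp[sim$clasping$mouse_id %in% wt_ids]))
  expect_false(any(sim$bursts$mouse_id %in% wt_ids))
  # beta bursts appear only at or after the per-mouse onset age
  if (nrow(sim$bursts)) {
    on <- sim$onsets$beta_onset_weeks[match(sim$bursts$mouse_id,
                                            sim$onsets$mouse_id)]
    expect_true(all(sim$bursts$age_weeks >= on))
  }

  # same seed: byte-identical manifest and EDFs; different seed differs
  dir2 <- withr::local_tempdir()
  simulate_cohort(dir2, n_r61 = 3, n_wt = 2,
                  session_ages_weeks = c(10, 14), seed = 4,
                  config_overrides = list(duration_s = 30, fs_signal = 200))
  same <- function(f, d1, d2) identical(
    readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
    readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  expect_true(same("manifest.csv", dir, dir2))
  expect_true(same(sim$manifest$path[1], dir, dir2))
  dir3 <- withr::local_tempdir()
  simulate_cohort(dir3, n_r61 = 3, n_wt = 2,
                  session_ages_weeks = c(10, 14), seed = 5,
                  config_overrides = list(duration_s = 30, fs_signal = 200))
  expect_false(same(sim$manifest$path[1], dir, dir3))

  expect_error(simulate_cohort(withr::local_tempdir(),
                               session_ages_weeks = numeric(0)),
               class = "betasleep_config_error")
})
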