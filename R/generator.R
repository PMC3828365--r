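#' Generator configuration for synthetic sleep-EEG sessions
#'
#' Builds the parameter set from which synthetic sessions and cohorts are
#' simulated: a semi-Markov vigilance-state model (exponential dwell times),
#' state-gated oscillations on a 1/f^2 Gaussian background, state-dependent
#' EMG and locomotion, and — for the transgenic preset — beta bursts whose
#' rate, duration and amplitude increase from active waking through SWS to
#' REM sleep, with an age model that lowers the burst center frequency and
#' raises its amplitude as the animal ages.
#'
#' Presets: `genotype = "WT"` has theta at 7.5 Hz and no beta bursts at any
#' age; `genotype = "R6/1"` has theta at 6.75 Hz and beta bursts whose
#' center frequency falls linearly 27 -> 23 Hz and whose amplitude triples
#' from 9 to 26 weeks of age. At the default symptomatic age (17.5 weeks)
#' the center frequency is exactly 25 Hz.
#'
#' @param genotype `"R6/1"` or `"WT"`.
#' @param age_weeks Age of the simulated animal in weeks (default 17.5, the
#'   mid-symptomatic point of the age model).
#' @param fs_signal Signal sampling rate, Hz (default 500; 2000 supported).
#' @param duration_s Session duration in seconds (default 600).
#' @param ... Named overrides for any configuration field (see the returned
#'   list); unknown names are an error.
#'
#' @return An object of class `generator_config` (a named list).
#' @export
generator_config <- function(genotype = c("R6/1", "WT"), age_weeks = 17.5,
                             fs_signal = 500, duration_s = 600, ...) {
  genotype <- match.arg(genotype)
  st <- VIGILANCE_STATES
  named <- function(...) stats::setNames(c(...), st)
  trans <- matrix(0, 4, 4, dimnames = list(st, st))
  trans["ACTIVE_WAKE", "QUIET_WAKE"] <- 1
  trans["QUIET_WAKE", c("ACTIVE_WAKE", "SWS")] <- c(0.25, 0.75)
  trans["SWS", c("ACTIVE_WAKE", "QUIET_WAKE", "REM")] <- c(0.15, 0.25, 0.6)
  trans["REM", c("ACTIVE_WAKE", "QUIET_WAKE")] <- c(0.4, 0.6)

  cfg <- list(
    genotype = genotype,
    age_weeks = age_weeks,
    fs_signal = fs_signal,
    fs_position = 50,
    duration_s = duration_s,
    # --- state dynamics -----------------------------------------------------
    dwell_mean_s = named(40, 25, 75, 50),
    transitions = trans,
    initial_state = "SWS",
    # --- background and oscillations (amplitudes in uV) ---------------------
    bg_exponent = 2,
    bg_rms_uv = list(hippocampus_lfp = named(40, 70, 100, 50),
                     frontal_eeg     = named(20, 35, 50, 25)),
    theta_freq_hz = if (genotype == "WT") 7.5 else 6.75,
    theta_amp_uv = named(40, 0, 0, 45),
    theta_frontal_gain = 0.5,
    theta_jitter_frac = 0.05,
    sws_broadband_hz = c(2, 8),
    sws_broadband_rms_uv = c(hippocampus_lfp = 100, frontal_eeg = 50),
    emg_rms_uv = named(30, 15, 6, 3),
    # --- beta bursts ---------------------------------------------------------
    beta_rate_per_min = if (genotype == "WT") named(0, 0, 0, 0)
                        else named(1, 8, 12, 15),
    beta_dur_s = named(0.3, 0.7, 1.0, 1.8),
    beta_amp_factor = named(0.3, 1.0, 1.5, 1.8),
    beta_amp_base_uv = 15,          # at 9 weeks; triples by 26 weeks
    beta_age_range_weeks = c(9, 26),
    beta_cf_range_hz = c(27, 23),   # falls linearly over the age range
    beta_cf_jitter_sd_hz = 1.0,
    beta_amp_jitter_sdlog = 0.15,
    beta_dur_shape = 6,             # gamma shape for burst durations
    beta_hip_gain = 0.6,
    # --- waking delta events coupled to beta (quiet waking only) ------------
    delta_couple_prob = 0.85,
    delta_freq_hz = c(2.5, 4.5),
    delta_amp_uv = 60,
    delta_dur_factor = 1.5,
    # --- movement -----------------------------------------------------------
    speed_cm_s = named(8, 0.2, 0.05, 0.05),
    cage_cm = c(33, 15),
    pos_jitter_cm = 0.005,
    # --- longitudinal design ------------------------------------------------
    beta_onset_range_weeks = c(10, 19),
    clasp_lag_weeks = 6.67,
    clasp_lag_sd_weeks = 0
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop_betasleep(paste0("unknown config field(s): ",
                            paste(unknown, collapse = ", ")),
                     "betasleep_config_error")
    cfg <- modifyList(cfg, dots)
  }
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  st <- VIGILANCE_STATES
  nonneg <- c(cfg$dwell_mean_s, cfg$beta_rate_per_min, cfg$beta_dur_s,
              cfg$beta_amp_factor, cfg$emg_rms_uv, cfg$theta_amp_uv,
              unlist(cfg$bg_rms_uv), cfg$sws_broadband_rms_uv,
              cfg$speed_cm_s)
  if (any(!is.finite(nonneg)) || any(nonneg < 0))
    stop_betasleep("rates, durations and amplitudes must be >= 0",
                   "betasleep_config_error")
  if (any(cfg$dwell_mean_s <= 0))
    stop_betasleep("dwell means must be > 0", "betasleep_config_error")
  r <- cfg$beta_rate_per_min
  if (cfg$genotype == "WT" && any(r > 0))
    stop_betasleep("WT preset must have zero beta burst rate",
                   "betasleep_config_error")
  if (cfg$genotype == "R6/1" && any(r > 0)) {
    ok <- r[["ACTIVE_WAKE"]] < r[["QUIET_WAKE"]] &&
      r[["QUIET_WAKE"]] <= r[["SWS"]] && r[["SWS"]] <= r[["REM"]]
    if (!ok)
      stop_betasleep(
        "R6/1 beta rates must satisfy ACTIVE_WAKE < QUIET_WAKE <= SWS <= REM",
        "betasleep_config_error")
  }
  tr <- cfg$transitions
  if (!identical(dim(tr), c(4L, 4L)) ||
      !setequal(rownames(tr), st) || !setequal(colnames(tr), st))
    stop_betasleep("transitions must be a 4x4 matrix over the state alphabet",
                   "betasleep_config_error")
  if (any(tr < 0))
    stop_betasleep("transition probabilities must be >= 0",
                   "betasleep_config_error")
  invisible(cfg)
}

# Beta-burst center frequency (Hz) at a given age: linear over the age range,
# clamped at its ends.
beta_center_freq <- function(cfg, age_weeks = cfg$age_weeks) {
  a <- cfg$beta_age_range_weeks
  f <- cfg$beta_cf_range_hz
  frac <- pmin(pmax((age_weeks - a[1]) / (a[2] - a[1]), 0), 1)
  f[1] + frac * (f[2] - f[1])
}

# Beta-burst base amplitude (uV) at a given age: linear, tripling over the
# age range.
beta_amp_uv <- function(cfg, age_weeks = cfg$age_weeks) {
  a <- cfg$beta_age_range_weeks
  frac <- pmin(pmax((age_weeks - a[1]) / (a[2] - a[1]), 0), 1)
  cfg$beta_amp_base_uv * (1 + 2 * frac)
}

#' Simulate a ground-truth vigilance-state sequence
#'
#' Draws a semi-Markov chain: exponential dwell times with state-specific
#' means, then a jump according to the transition matrix. The continuous
#' path is discretized onto the spectrogram window grid (2-s epochs starting
#' at t = 1 s, one per 4-s/50%-overlap analysis window), taking the state at
#' each epoch center. The raw bouts are attached as attribute `"bouts"`
#' (a data frame with `state`, `start_s`, `end_s`).
#'
#' @param config A [generator_config()].
#' @param duration_s Session duration in seconds (>= 6 so that at least one
#'   analysis window fits).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#'
#' @return A [hypnogram()] with `epoch_len_s = 2`, `start_time_s = 1` and
#'   `floor((duration_s - 4)/2) + 1` labels.
#' @export
simulate_state_sequence <- function(config, duration_s = config$duration_s,
                                    seed = NULL) {
  if (!is.numeric(duration_s) || duration_s < 6)
    stop_betasleep("duration_s must be >= 6 s", "betasleep_config_error")
  tr <- config$transitions
  state <- config$initial_state
  if (!state %in% VIGILANCE_STATES)
    stop_betasleep("initial_state must be one of the four states",
                   "betasleep_config_error")
  with_seed_opt(seed, {
    cap <- max(64L, ceiling(duration_s / min(config$dwell_mean_s)) * 4L)
    states <- character(cap); starts <- numeric(cap)
    nb <- 0L
    t <- 0
    while (t < duration_s) {
      nb <- nb + 1L
      if (nb > length(states)) {       # grow by doubling
        states <- c(states, character(length(states)))
        starts <- c(starts, numeric(length(starts)))
      }
      states[nb] <- state; starts[nb] <- t
      t <- t + rexp(1, rate = 1 / config$dwell_mean_s[[state]])
      p <- tr[state, ]
      if (sum(p) <= 0)
        stop_betasleep(sprintf(
          "state %s is reached but has no outgoing transition", state),
          "betasleep_config_error")
      state <- sample(colnames(tr), 1, prob = p)
    }
    states <- states[seq_len(nb)]; starts <- starts[seq_len(nb)]
    ends <- c(starts[-1], duration_s)
    bouts <- data.frame(state = states, start_s = starts, end_s = ends)
    # merge consecutive identical states (self-loops)
    keep <- c(TRUE, bouts$state[-1] != bouts$state[-nrow(bouts)])
    grp <- cumsum(keep)
    merged <- data.frame(
      state = bouts$state[keep],
      start_s = bouts$start_s[keep],
      end_s = tapply(bouts$end_s, grp, max))
    rownames(merged) <- NULL
    n_ep <- floor((duration_s - 4) / 2) + 1
    centers <- 2 * seq_len(n_ep)
    idx <- findInterval(centers, merged$start_s)
    hyp <- hypnogram(merged$state[idx], epoch_len_s = 2, start_time_s = 1)
    attr(hyp, "bouts") <- merged
    hyp
  })
}

# Unit-RMS Gaussian noise with power spectral density proportional to
# f^(-exponent), flat below f_lo to avoid the DC blow-up.
colored_noise <- function(n, fs, exponent, f_lo = 0.5) {
  if (n < 2) return(rnorm(n))
  x <- rnorm(n)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided axis
  h <- pmax(f, f_lo)^(-exponent / 2)
  h[1] <- 0
  y <- Re(fft(fft(x) * h, inverse = TRUE)) / n
  y / max(sd(y), .Machine$double.eps)
}

# Unit-RMS band-limited noise, PSD ~ f^-1.4 inside [lo, hi] (wide-band
# activity with the low ranges prevalent), raised-cosine edges of 0.5 Hz.
band_noise <- function(n, fs, lo, hi) {
  if (n < 2) return(rnorm(n))
  x <- rnorm(n)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  h <- rep(0, n)
  inside <- f >= lo & f <= hi
  h[inside] <- f[inside]^(-0.7)
  ramp <- 0.5
  lo_edge <- f >= lo - ramp & f < lo
  h[lo_edge] <- lo^(-0.7) * 0.5 * (1 + cos(pi * (lo - f[lo_edge]) / ramp))
  hi_edge <- f > hi & f <= hi + ramp
  h[hi_edge] <- hi^(-0.7) * 0.5 * (1 + cos(pi * (f[hi_edge] - hi) / ramp))
  y <- Re(fft(fft(x) * h, inverse = TRUE)) / n
  y / max(sd(y), .Machine$double.eps)
}

#' Synthesize session signals from a hypnogram
#'
#' Each signal channel is built as 1/f Gaussian background plus state-gated
#' oscillations: a hippocampal theta sinusoid (5 % slow frequency jitter)
#' during REM and active waking (attenuated copy on the frontal channel,
#' mimicking volume conduction), wide-band 2-8 Hz activity during SWS,
#' Hann-enveloped beta bursts at the age-dependent center frequency injected
#' on frontal and hippocampal channels at the state's configured rate, EMG
#' as Gaussian noise at the state RMS, and a position random walk whose
#' speed follows the state. During quiet waking each beta burst is
#' accompanied (with probability `delta_couple_prob`) by a hippocampal
#' 2.5-4.5 Hz delta event, producing the positive delta-beta / negative
#' theta-beta power comodulation seen in the waking state.
#'
#' @param hyp A [hypnogram()] on the analysis grid (as produced by
#'   [simulate_state_sequence()]).
#' @param config A [generator_config()]; `config$fs_signal` must be at least
#'   200 Hz (Nyquist margin over the beta band).
#' @param seed Integer seed or `NULL`.
#' @param mouse_id Identifier for the returned session.
#'
#' @return A list with `session` (a [session_recording()]) and `bursts`
#'   (data frame of ground-truth beta burst intervals: `start_s`, `end_s`,
#'   `center_hz`, `amp_uv`, `state`).
#' @export
synthesize_signals <- function(hyp, config, seed = NULL, mouse_id = "sim") {
  fs <- config$fs_signal
  if (fs < 200)
    stop_betasleep("fs_signal must be >= 200 Hz", "betasleep_config_error")
  n_ep <- length(hyp$labels)
  duration_s <- hyp$start_time_s * 2 + n_ep * hyp$epoch_len_s
  n <- round(duration_s * fs)
  st <- VIGILANCE_STATES

  with_seed_opt(seed, {
    t <- (seq_len(n) - 1) / fs
    idx <- pmin(pmax(floor((t - hyp$start_time_s) / hyp$epoch_len_s) + 1, 1),
                n_ep)
    state_vec <- hyp$labels[idx]

    zero_sig <- function() numeric(n)
    frontal <- zero_sig(); hip <- zero_sig()

    # 1/f background
    for (ch in c("frontal_eeg", "hippocampus_lfp")) {
      bg <- colored_noise(n, fs, config$bg_exponent) *
        config$bg_rms_uv[[ch]][state_vec]
      if (ch == "frontal_eeg") frontal <- frontal + bg else hip <- hip + bg
    }

    # theta with slow 5% frequency jitter (REM + active waking)
    f0 <- config$theta_freq_hz
    if (f0 > 0 && any(config$theta_amp_uv > 0)) {
      g <- moving_average(rnorm(n), round(2 * fs))
      g <- g / max(sd(g), .Machine$double.eps)
      finst <- f0 * (1 + config$theta_jitter_frac * g)
      phase <- 2 * pi * cumsum(finst) / fs
      th <- sin(phase)
      amp <- config$theta_amp_uv[state_vec]
      hip <- hip + th * amp
      frontal <- frontal + th * amp * config$theta_frontal_gain
    }

    # SWS wide-band 2-8 Hz activity
    if (any(config$sws_broadband_rms_uv > 0)) {
      bb <- band_noise(n, fs, config$sws_broadband_hz[1],
                       config$sws_broadband_hz[2])
      mask <- as.numeric(state_vec == "SWS")
      frontal <- frontal + bb * mask * config$sws_broadband_rms_uv[["frontal_eeg"]]
      hip <- hip + bb * mask * config$sws_broadband_rms_uv[["hippocampus_lfp"]]
    }

    # beta bursts per state bout
    runs <- rle(state_vec)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1
    bursts <- list()
    amp_age <- beta_amp_uv(config)
    cf_age <- beta_center_freq(config)
    for (j in seq_along(runs$values)) {
      s <- runs$values[j]
      rate <- config$beta_rate_per_min[[s]]
      if (rate <= 0) next
      t0 <- t[run_start[j]]; t1 <- t[run_end[j]] + 1 / fs
      len_s <- t1 - t0
      k <- rpois(1, rate * len_s / 60)
      if (k == 0) next
      b_start <- t0 + sort(runif(k)) * len_s
      b_dur <- rgamma(k, shape = config$beta_dur_shape,
                      scale = config$beta_dur_s[[s]] / config$beta_dur_shape)
      b_dur <- pmax(b_dur, 0.1)
      b_end <- pmin(b_start + b_dur, t1)
      b_cf <- rnorm(k, cf_age, config$beta_cf_jitter_sd_hz)
      b_amp <- amp_age * config$beta_amp_factor[[s]] *
        rlnorm(k, 0, config$beta_amp_jitter_sdlog)
      b_phi <- runif(k, 0, 2 * pi)
      for (b in seq_len(k)) {
        i0 <- max(1L, ceiling(b_start[b] * fs) + 1L)
        i1 <- min(n, floor(b_end[b] * fs))
        if (i1 - i0 < 4) next
        tt <- t[i0:i1] - b_start[b]
        env <- 0.5 * (1 - cos(2 * pi * tt / (b_end[b] - b_start[b])))
        w <- b_amp[b] * env * cos(2 * pi * b_cf[b] * tt + b_phi[b])
        frontal[i0:i1] <- frontal[i0:i1] + w
        hip[i0:i1] <- hip[i0:i1] + w * config$beta_hip_gain
        bursts[[length(bursts) + 1L]] <- data.frame(
          start_s = b_start[b], end_s = b_end[b], center_hz = b_cf[b],
          amp_uv = b_amp[b], state = s)
        # coupled hippocampal delta event during quiet waking
        if (s == "QUIET_WAKE" && config$delta_amp_uv > 0 &&
            runif(1) < config$delta_couple_prob) {
          d_dur <- (b_end[b] - b_start[b]) * config$delta_dur_factor
          d_start <- max(t0, b_start[b] - (d_dur - (b_end[b] - b_start[b])) / 2)
          d_end <- min(t1, d_start + d_dur)
          di0 <- max(1L, ceiling(d_start * fs) + 1L)
          di1 <- min(n, floor(d_end * fs))
          if (di1 - di0 >= 4) {
            dt <- t[di0:di1] - d_start
            denv <- 0.5 * (1 - cos(2 * pi * dt / (d_end - d_start)))
            dfq <- runif(1, config$delta_freq_hz[1], config$delta_freq_hz[2])
            hip[di0:di1] <- hip[di0:di1] +
              config$delta_amp_uv * denv * cos(2 * pi * dfq * dt)
          }
        }
      }
    }
    bursts <- if (length(bursts)) do.call(rbind, bursts) else
      data.frame(start_s = numeric(0), end_s = numeric(0),
                 center_hz = numeric(0), amp_uv = numeric(0),
                 state = character(0))

    emg <- rnorm(n) * config$emg_rms_uv[state_vec]

    # position random walk, speed set by state, folded into the cage
    np <- round(duration_s * config$fs_position)
    tp <- (seq_len(np) - 1) / config$fs_position
    pidx <- pmin(pmax(floor((tp - hyp$start_time_s) / hyp$epoch_len_s) + 1, 1),
                 n_ep)
    pstate <- hyp$labels[pidx]
    spd <- config$speed_cm_s[pstate] * rlnorm(np, -0.02, 0.2)
    heading <- cumsum(rnorm(np, 0, 0.3))
    dx <- spd / config$fs_position * cos(heading)
    dy <- spd / config$fs_position * sin(heading)
    fold <- function(p, L) {
      if (L <= 0) return(rep(0, length(p)))
      m <- p %% (2 * L)
      L - abs(m - L)
    }
    x <- fold(config$cage_cm[1] / 2 + cumsum(dx), config$cage_cm[1]) +
      rnorm(np, 0, config$pos_jitter_cm)
    y <- fold(config$cage_cm[2] / 2 + cumsum(dy), config$cage_cm[2]) +
      rnorm(np, 0, config$pos_jitter_cm)

    session <- session_recording(
      mouse_id = mouse_id, genotype = config$genotype,
      age_weeks = config$age_weeks,
      channels = list(frontal_eeg = frontal, hippocampus_lfp = hip, emg = emg),
      fs_signal = fs, position = cbind(x = x, y = y),
      fs_position = config$fs_position, duration_s = duration_s)
    list(session = session, bursts = bursts)
  })
}

#' Simulate one complete session
#'
#' Convenience wrapper: draws the state sequence, then the signals, under a
#' single seed.
#'
#' @inheritParams synthesize_signals
#' @param config A [generator_config()].
#' @param seed Integer seed or `NULL`.
#'
#' @return A list with `session`, `hypnogram` (ground truth) and `bursts`.
#' @export
simulate_session <- function(config, seed = NULL, mouse_id = "sim") {
  with_seed_opt(seed, {
    hyp <- simulate_state_sequence(config, config$duration_s, seed = NULL)
    out <- synthesize_signals(hyp, config, seed = NULL, mouse_id = mouse_id)
    list(session = out$session, hypnogram = hyp, bursts = out$bursts)
  })
}

#' Simulate a longitudinal cohort and write it to disk
#'
#' For each transgenic mouse a beta-onset age is drawn uniformly from
#' `beta_onset_range_weeks` and a clasping age is set to onset plus
#' `clasp_lag_weeks`; beta bursts are present only in sessions at or after
#' the onset age. Wild-type mice never clasp and never have bursts. Sessions
#' are written as EDF files with a CSV manifest, clasping observations and
#' ground-truth tables alongside.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_r61,n_wt Number of mice per genotype.
#' @param session_ages_weeks Increasing vector of recording ages (weeks).
#' @param seed Integer seed; all randomness (onsets and per-session
#'   simulation) derives from it.
#' @param config_overrides Named list of [generator_config()] overrides
#'   applied to every session (e.g. a shorter `duration_s` for testing).
#'
#' @return Invisibly, a list with `manifest`, `clasping`, `onsets` and
#'   `bursts` data frames plus the file paths written.
#' @export
simulate_cohort <- function(out_dir, n_r61 = 10, n_wt = 8,
                            session_ages_weeks = c(9, 13, 17, 22, 26),
                            seed = 1, config_overrides = list()) {
  if (!length(session_ages_weeks))
    stop_betasleep("session_ages_weeks must be non-empty",
                   "betasleep_config_error")
  if (any(diff(session_ages_weeks) <= 0))
    stop_betasleep("session ages must be strictly increasing",
                   "betasleep_config_error")
  if (n_r61 + n_wt < 1)
    stop_betasleep("need at least one mouse", "betasleep_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ids <- c(sprintf("R61_%02d", seq_len(n_r61)),
           sprintf("WT_%02d", seq_len(n_wt)))
  genos <- c(rep("R6/1", n_r61), rep("WT", n_wt))

  base_cfg <- do.call(generator_config,
                      c(list(genotype = "R6/1"), config_overrides))
  onsets <- withr::with_seed(as.integer(seed), {
    on <- runif(n_r61, base_cfg$beta_onset_range_weeks[1],
                base_cfg$beta_onset_range_weeks[2])
    lag <- base_cfg$clasp_lag_weeks +
      if (base_cfg$clasp_lag_sd_weeks > 0)
        rnorm(n_r61, 0, base_cfg$clasp_lag_sd_weeks) else 0
    data.frame(mouse_id = ids[seq_len(n_r61)],
               beta_onset_weeks = on,
               clasp_onset_weeks = on + lag)
  })

  manifest <- list(); clasping <- list(); bursts <- list()
  for (m in seq_along(ids)) {
    for (a in seq_along(session_ages_weeks)) {
      age <- session_ages_weeks[a]
      ov <- config_overrides
      cfg <- do.call(generator_config,
                     c(list(genotype = genos[m], age_weeks = age), ov))
      if (genos[m] == "R6/1" && age < onsets$beta_onset_weeks[m]) {
        rates <- cfg$beta_rate_per_min; rates[] <- 0
        cfg$beta_rate_per_min <- rates
        cfg$delta_amp_uv <- 0
      }
      sseed <- (as.numeric(seed) + 7919 * m + 104729 * a) %% 2147483647
      sim <- simulate_session(cfg, seed = sseed, mouse_id = ids[m])
      fname <- sprintf("%s_w%05.1f.edf", gsub("/", "", ids[m]), age)
      path <- file.path(out_dir, fname)
      write_session(sim$session, path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        mouse_id = ids[m], genotype = genos[m], age_weeks = age, path = fname)
      if (nrow(sim$bursts)) {
        b <- sim$bursts
        b$mouse_id <- ids[m]; b$age_weeks <- age
        bursts[[length(bursts) + 1L]] <- b[, c("mouse_id", "age_weeks",
                                               "start_s", "end_s",
                                               "center_hz", "state")]
      }
    }
    clasp_age <- if (genos[m] == "R6/1")
      onsets$clasp_onset_weeks[match(ids[m], onsets$mouse_id)] else Inf
    clasping[[m]] <- clasping_record(ids[m], session_ages_weeks,
                                     session_ages_weeks >= clasp_age)
  }
  manifest <- do.call(rbind, manifest)
  clasping <- do.call(rbind, clasping)
  bursts <- if (length(bursts)) do.call(rbind, bursts) else
    data.frame(mouse_id = character(0), age_weeks = numeric(0),
               start_s = numeric(0), end_s = numeric(0),
               center_hz = numeric(0), state = character(0))

  paths <- list(manifest = file.path(out_dir, "manifest.csv"),
                clasping = file.path(out_dir, "clasping.csv"),
                onsets = file.path(out_dir, "truth_onsets.csv"),
                bursts = file.path(out_dir, "truth_bursts.csv"))
  hdr <- sprintf("seed=%d", as.integer(seed))
  write_csv_commented(manifest, paths$manifest, hdr)
  write_csv_commented(clasping, paths$clasping, hdr)
  write_csv_commented(onsets, paths$onsets, hdr)
  write_csv_commented(bursts, paths$bursts, hdr)
  invisible(list(manifest = manifest, clasping = clasping, onsets = onsets,
                 bursts = bursts, paths = paths, dir = out_dir))
}
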