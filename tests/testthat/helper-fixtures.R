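# Shared fixtures, built once per test run and memoised: ten 10-minute
# default-preset sessions per genotype (seeds 1001-1010) analyzed end to
# end, and one full-size longitudinal cohort (seed 1).

.fixture_env <- new.env(parent = emptyenv())

# Per-seed session fixtures. Each element keeps the analyzed result and the
# ground-truth hypnogram; raw traces are dropped to bound memory.
default_sessions <- function(genotype) {
  key <- paste0("sessions_", gsub("/", "", genotype))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- lapply(1:10, function(i) {
      cfg <- generator_config(genotype)
      sim <- simulate_session(cfg, seed = 1000 + i)
      res <- run_session(sim$session)
      list(seed = 1000 + i, result = res, truth = sim$hypnogram)
    })
  }
  .fixture_env[[key]]
}

# Full default cohort (10 R6/1 + 8 WT, monthly sessions 9-26 weeks),
# simulated to a temporary directory and analyzed.
default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    dir <- file.path(tempdir(), "betasleep-cohort-fixture")
    sim <- simulate_cohort(dir, seed = 1)
    res <- run_cohort(file.path(dir, "manifest.csv"),
                      file.path(dir, "clasping.csv"))
    .fixture_env$cohort <- list(sim = sim, result = res)
  }
  .fixture_env$cohort
}

# Small deterministic session for I/O and pipeline plumbing tests.
small_session <- function(seed = 7, duration_s = 120, fs = 200) {
  cfg <- generator_config("R6/1", duration_s = duration_s, fs_signal = fs)
  simulate_session(cfg, seed = seed)
}

# Hand-built spectrogram object (uniform grid) for unit tests that need
# full control over the power matrix.
make_spectrogram <- function(power, freqs, hop_s = 2, window_len_s = 4) {
  structure(list(power = power, freqs = freqs,
                 window_times = window_len_s / 2 +
                   (seq_len(nrow(power)) - 1) * hop_s,
                 fs = 2 * max(freqs), window_len_s = window_len_s,
                 hop_s = hop_s),
            class = "spectrogram")
}

# Hand-built normalized spectrum.
make_spectrum <- function(values, freqs,
                          normalization_range = c(0.5, 100)) {
  m <- freqs >= normalization_range[1] - 1e-9 &
    freqs <= normalization_range[2] + 1e-9
  structure(list(values = values / sum(values[m]), freqs = freqs,
                 state = "SWS", n_windows = 1L,
                 normalization_range = normalization_range),
            class = "psd_spectrum")
}
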