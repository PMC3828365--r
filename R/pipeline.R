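#' Run the single-session analysis
#'
#' End-to-end per-session pipeline: spectrograms of the frontal and
#' hippocampal channels, per-epoch EMG RMS and movement speed, automated
#' vigilance-state scoring, state-conditioned normalized spectra for both
#' channels, and beta-peak detection on the frontal spectrum of each state.
#' Deterministic given its inputs.
#'
#' @param session A [session_recording()].
#' @param thresholds A [scoring_thresholds()].
#' @param bands Band list as from [spectral_bands()].
#' @param prominence Beta-peak presence threshold (see [detect_beta_peak()]).
#' @param min_windows Minimum number of spectrogram windows a state must
#'   have before its spectrum is estimated and analyzed (default 15, i.e.
#'   30 s of data; a state-averaged spectrum from fewer windows is too noisy
#'   to support peak detection).
#' @param out_dir Optional directory; when given, the hypnogram, spectra and
#'   a per-state results table are written as CSV with a configuration-hash
#'   header comment.
#'
#' @return An object of class `session_result`: `hypnogram` (scored),
#'   `spectra` (list `frontal` / `hippocampus`, each a list by state),
#'   `results` (data frame, one row per scored state: `mouse_id`,
#'   `genotype`, `age_weeks`, `state`, `n_windows`, `band_power_beta`
#'   (frontal 15-40 Hz), `band_power_theta` (hippocampal 4-8 Hz),
#'   `beta_present`, `beta_peak_freq`, `beta_peak_power`,
#'   `beta_prominence`), and the two spectrograms.
#' @export
run_session <- function(session, thresholds = scoring_thresholds(),
                        bands = spectral_bands(), prominence = 2,
                        min_windows = 15, out_dir = NULL) {
  stopifnot(inherits(session, "session_recording"))
  fs <- session$fs_signal
  spg_f <- compute_spectrogram(session$channels$frontal_eeg, fs)
  spg_h <- compute_spectrogram(session$channels$hippocampus_lfp, fs)
  n_ep <- nrow(spg_h$power)
  emg <- epoch_emg_rms(session$channels$emg, fs, n_ep)
  spd_epochs <- if (!is.null(session$position)) {
    speed <- compute_movement(session$position, session$fs_position)
    epoch_speed(speed, session$fs_position, n_ep)
  } else rep(0, n_ep)
  hyp <- score_states(spg_h, emg, spd_epochs, thresholds)

  counts <- table(factor(hyp$labels, VIGILANCE_STATES))
  states <- VIGILANCE_STATES[counts >= min_windows]
  spectra <- list(frontal = list(), hippocampus = list())
  rows <- list()
  for (s in states) {
    sf <- state_spectrum(spg_f, hyp, s, bands$normalization)
    sh <- state_spectrum(spg_h, hyp, s, bands$normalization)
    spectra$frontal[[s]] <- sf
    spectra$hippocampus[[s]] <- sh
    bp <- detect_beta_peak(sf, band = bands$beta_sum, threshold = prominence)
    rows[[s]] <- data.frame(
      mouse_id = session$mouse_id, genotype = session$genotype,
      age_weeks = session$age_weeks, state = s, n_windows = sf$n_windows,
      band_power_beta = band_power(sf, bands$beta_sum[1], bands$beta_sum[2]),
      band_power_theta = band_power(sh, bands$theta_sum[1],
                                    bands$theta_sum[2]),
      beta_present = bp$present, beta_peak_freq = bp$peak_freq,
      beta_peak_power = bp$peak_power, beta_prominence = bp$prominence)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- structure(list(hypnogram = hyp, spectra = spectra,
                        results = results, spectrogram_frontal = spg_f,
                        spectrogram_hippocampus = spg_h,
                        session = session[c("mouse_id", "genotype",
                                            "age_weeks", "duration_s")]),
                   class = "session_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("%s_w%05.1f", gsub("/", "", session$mouse_id),
                   session$age_weeks)
    hdr <- c(sprintf("config_hash=%s", config_hash(list(thresholds, bands,
                                                        prominence))),
             sprintf("mouse=%s genotype=%s age_weeks=%g", session$mouse_id,
                     session$genotype, session$age_weeks))
    write_hypnogram_csv(hyp, file.path(out_dir,
                                       paste0(tag, "_hypnogram.csv")), hdr)
    write_spectra_csv(spectra$frontal,
                      file.path(out_dir, paste0(tag, "_spectra_frontal.csv")),
                      hdr)
    write_spectra_csv(spectra$hippocampus,
                      file.path(out_dir,
                                paste0(tag, "_spectra_hippocampus.csv")), hdr)
    write_csv_commented(results,
                        file.path(out_dir, paste0(tag, "_results.csv")), hdr)
  }
  out
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s (%s, %g wk)\n", x$session$mouse_id,
              x$session$genotype, x$session$age_weeks))
  print(x$results[, c("state", "n_windows", "band_power_beta",
                      "beta_present", "beta_peak_freq")])
  invisible(x)
}

#' Run the cohort-level analysis
#'
#' Reads a session manifest (CSV columns `mouse_id,genotype,age_weeks,path`,
#' EDF paths relative to the manifest), runs [run_session()] on every
#' session, and assembles the cohort statistics: the per-mouse/session/state
#' table, mouse-level beta presence (REM-state detection, the state in which
#' the oscillation is strongest), the genotype-by-presence contingency table
#' with its Pearson chi-square, beta-onset ages, onset-versus-clasping
#' precedence, and a genotype-by-state ANOVA of beta band power at the
#' oldest recorded age. Sessions that fail are reported and skipped; the
#' run continues.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param clasping_path Path to the clasping CSV
#'   (`mouse_id,age_weeks,clasp`).
#' @param thresholds,bands,prominence Passed to [run_session()].
#' @param out_dir Optional output directory for the cohort CSVs and a plain
#'   text summary.
#' @param seed Seed recorded in output headers (the analysis itself is
#'   deterministic).
#'
#' @return An object of class `cohort_result`: `table` (the cohort data
#'   frame), `presence` (per-mouse), `contingency`, `chi_square`, `onsets`,
#'   `precedence` ([precedence_summary()] or `NULL`), `anova` (or `NULL`),
#'   `failures` (character).
#' @export
run_cohort <- function(manifest_path, clasping_path,
                       thresholds = scoring_thresholds(),
                       bands = spectral_bands(), prominence = 2,
                       out_dir = NULL, seed = NA) {
  manifest <- read_csv_commented(manifest_path)
  need <- c("mouse_id", "genotype", "age_weeks", "path")
  if (!all(need %in% names(manifest)))
    stop_betasleep("manifest needs columns mouse_id,genotype,age_weeks,path",
                   "betasleep_format_error")
  clasping <- read_csv_commented(clasping_path)
  root <- dirname(manifest_path)

  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    res <- tryCatch({
      p <- if (file.exists(m$path)) m$path else file.path(root, m$path)
      ses <- read_session(p, m$mouse_id, m$genotype, m$age_weeks)
      run_session(ses, thresholds, bands, prominence)$results
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s @ %g wk: %s", m$mouse_id,
                                       m$age_weeks, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    stop_betasleep("no session could be analyzed", "betasleep_io_error")
  tab <- do.call(rbind, rows)

  # session-level presence: the REM-state detection
  rem <- tab[tab$state == "REM", , drop = FALSE]
  mice <- unique(tab[, c("mouse_id", "genotype")])
  presence <- do.call(rbind, lapply(seq_len(nrow(mice)), function(i) {
    id <- mice$mouse_id[i]
    mrem <- rem[rem$mouse_id == id, , drop = FALSE]
    mrem <- mrem[order(mrem$age_weeks), , drop = FALSE]
    onset <- if (nrow(mrem))
      beta_onset_age(mrem$age_weeks, mrem$beta_present) else NA_real_
    data.frame(mouse_id = id, genotype = mice$genotype[i],
               beta_ever = isTRUE(any(mrem$beta_present)),
               beta_onset_weeks = onset)
  }))

  contingency <- matrix(
    c(sum(presence$genotype == "R6/1" & presence$beta_ever),
      sum(presence$genotype == "R6/1" & !presence$beta_ever),
      sum(presence$genotype == "WT" & presence$beta_ever),
      sum(presence$genotype == "WT" & !presence$beta_ever)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("R6/1", "WT"), c("beta", "no_beta")))
  chi <- tryCatch(chi_square_2x2(contingency), error = function(e) NULL)

  prec <- if (nrow(clasping) && any(!is.na(presence$beta_onset_weeks)))
    tryCatch(precedence_summary(
      presence[, c("mouse_id", "beta_onset_weeks")], clasping),
      error = function(e) NULL) else NULL

  oldest <- max(tab$age_weeks)
  at_old <- tab[tab$age_weeks == oldest, , drop = FALSE]
  anova_tab <- tryCatch(
    two_way_anova(at_old$band_power_beta, at_old$genotype, at_old$state,
                  names_ab = c("genotype", "state")),
    error = function(e) NULL)

  out <- structure(list(table = tab, presence = presence,
                        contingency = contingency, chi_square = chi,
                        onsets = presence[, c("mouse_id",
                                              "beta_onset_weeks")],
                        precedence = prec, anova = anova_tab,
                        anova_age_weeks = oldest, failures = failures),
                   class = "cohort_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(sprintf("seed=%s", seed),
             sprintf("config_hash=%s",
                     config_hash(list(thresholds, bands, prominence))))
    write_csv_commented(tab, file.path(out_dir, "cohort_table.csv"), hdr)
    write_csv_commented(presence, file.path(out_dir, "beta_presence.csv"),
                        hdr)
    writeLines(c(paste0("# ", hdr), format_cohort_summary(out)),
               file.path(out_dir, "summary.txt"))
  }
  out
}

format_cohort_summary <- function(x) {
  lines <- c("Cohort summary", "==============", "",
             "Beta presence by genotype (REM-state detection):",
             utils::capture.output(print(x$contingency)))
  if (!is.null(x$chi_square))
    lines <- c(lines, sprintf("Chi-square(1) = %.4g, p = %.3g",
                              x$chi_square$statistic, x$chi_square$p))
  on <- x$presence$beta_onset_weeks
  on <- on[!is.na(on)]
  if (length(on))
    lines <- c(lines, "",
               sprintf("Beta onset: n = %d, range %g-%g wk, mean %.2f (SEM %.2f)",
                       length(on), min(on), max(on), mean(on),
                       sd(on) / sqrt(length(on))))
  if (!is.null(x$precedence))
    lines <- c(lines, "",
               sprintf("Precedence (clasp - beta onset): mean %.2f wk (SEM %.2f), beta first %d, clasp first %d of %d",
                       x$precedence$mean, x$precedence$sem,
                       x$precedence$n_beta_first, x$precedence$n_clasp_first,
                       x$precedence$n))
  if (!is.null(x$anova))
    lines <- c(lines, "",
               sprintf("Two-way ANOVA of beta power at %g wk:",
                       x$anova_age_weeks),
               utils::capture.output(print(x$anova, row.names = FALSE)))
  if (length(x$failures))
    lines <- c(lines, "", "Sessions skipped:", paste0("  ", x$failures))
  lines
}

#' @export
print.cohort_result <- function(x, ...) {
  writeLines(format_cohort_summary(x))
  invisible(x)
}
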