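# Minimal classic-EDF (European Data Format) reader/writer.
#
# Only the subset needed for electrophysiology sessions is supported:
# 16-bit samples, fixed 1-s data records, per-signal sampling rates.
# Physical min/max are written with 8-character ASCII fields; the writer
# quantizes against the *formatted* values so a round-trip reproduces samples
# to the declared amplitude resolution (range / 65535).

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

edf_num <- function(x, width) {
  s <- formatC(x, digits = 6, width = 1, format = "g")
  if (nchar(s) > width) s <- formatC(x, digits = 4, width = 1, format = "g")
  if (nchar(s) > width) s <- formatC(x, digits = 2, width = 1, format = "g")
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' @param path Output file path.
#' @param signals Named list of numeric vectors (one per signal).
#' @param fs Numeric vector of sampling rates, one per signal (recycled if
#'   scalar). Each `length(signal) / fs` must equal the same whole number of
#'   seconds (the record count).
#' @param phys_dim Character vector of physical dimensions (e.g. `"uV"`,
#'   `"cm"`), recycled.
#' @param patient,recording Free-text header fields (80 bytes each).
#'
#' @details The start date/time header fields are fixed so that identical
#'   inputs produce byte-identical files.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, phys_dim = "uV",
                      patient = "X", recording = "X") {
  ns <- length(signals)
  stopifnot(ns >= 1, !is.null(names(signals)))
  fs <- rep_len(fs, ns)
  phys_dim <- rep_len(phys_dim, ns)
  secs <- vapply(seq_len(ns), function(i) length(signals[[i]]) / fs[i],
                 numeric(1))
  n_rec <- unique(round(secs, 9))
  if (length(n_rec) != 1L || n_rec != round(n_rec) || n_rec < 1)
    stop_betasleep(
      "all signals must span the same whole number of seconds",
      "betasleep_format_error")
  n_rec <- as.integer(n_rec)
  spr <- as.integer(round(fs))          # samples per 1-s record

  pmin_s <- pmax_s <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]
    r <- range(x)
    if (!all(is.finite(r)))
      stop_betasleep("signals must be finite", "betasleep_format_error")
    if (r[1] == r[2]) r <- r + c(-1, 1)
    pmin_s[i] <- edf_num(r[1], 8)
    pmax_s[i] <- edf_num(r[2], 8)
    pmin <- as.numeric(pmin_s[i]); pmax <- as.numeric(pmax_s[i])
    # formatted bounds may have shrunk; widen to cover the data
    if (pmin > r[1]) { pmin_s[i] <- edf_num(r[1] - abs(r[1]) * 1e-4 - 1e-9, 8)
                       pmin <- as.numeric(pmin_s[i]) }
    if (pmax < r[2]) { pmax_s[i] <- edf_num(r[2] + abs(r[2]) * 1e-4 + 1e-9, 8)
                       pmax <- as.numeric(pmax_s[i]) }
    d <- round((x - pmin) / (pmax - pmin) * 65535 - 32768)
    dig[[i]] <- matrix(as.integer(pmin(pmax(d, -32768), 32767)),
                       nrow = spr[i], ncol = n_rec)
  }

  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(patient, 80))
  wr(edf_pad(recording, 80))
  wr("01.01.85"); wr("00.00.00")
  wr(edf_pad(as.character(header_bytes), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(as.character(n_rec), 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(as.character(ns), 4))
  wr(paste0(vapply(names(signals), edf_pad, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))                               # transducer
  wr(paste0(vapply(phys_dim, edf_pad, "", width = 8), collapse = ""))
  wr(paste0(pmin_s, collapse = ""))
  wr(paste0(pmax_s, collapse = ""))
  wr(strrep(edf_pad("-32768", 8), ns))
  wr(strrep(edf_pad("32767", 8), ns))
  wr(strrep(" ", 80 * ns))                               # prefiltering
  wr(paste0(vapply(spr, function(k) edf_pad(as.character(k), 8), ""),
            collapse = ""))
  wr(strrep(" ", 32 * ns))

  for (r in seq_len(n_rec)) {
    rec <- unlist(lapply(dig, function(m) m[, r]), use.names = FALSE)
    writeBin(rec, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return A list with elements `signals` (named list of numeric vectors in
#'   physical units), `fs` (named sampling rates), `phys_dim`,
#'   `duration_s`, and `resolution` (per-signal quantization step).
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop_betasleep(paste0("file not found: ", path), "betasleep_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16)
  fld(80)                                  # transducer
  phys_dim <- fld(8)
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)                                  # prefiltering
  spr <- as.integer(fld(8))
  fld(32)
  per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = per_rec * n_rec, size = 2L,
                 endian = "little")
  if (length(raw) != per_rec * n_rec)
    stop_betasleep("truncated EDF data section", "betasleep_format_error")
  offs <- c(0L, cumsum(spr))
  signals <- vector("list", ns)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns)) {
    pick <- as.vector(outer(offs[i] + seq_len(spr[i]),
                            (seq_len(n_rec) - 1L) * per_rec, `+`))
    signals[[i]] <- pmin[i] + (raw[pick] - dmin[i]) * scale[i]
  }
  names(signals) <- labels
  names(phys_dim) <- labels
  fs <- spr / rec_dur
  names(fs) <- labels
  res <- scale
  names(res) <- labels
  list(signals = signals, fs = fs, phys_dim = phys_dim,
       duration_s = n_rec * rec_dur, resolution = res)
}

#' Write / read a session recording as EDF
#'
#' The three signal channels are stored at `fs_signal` and the position track
#' as two extra signals (`pos_x`, `pos_y`) at `fs_position`. Mouse metadata
#' (id, genotype, age) travels in the session manifest CSV, not in the EDF,
#' so `read_session` takes it as arguments.
#'
#' @param session A [session_recording()].
#' @param path EDF file path.
#' @param mouse_id,genotype,age_weeks Metadata for the returned session
#'   (typically one row of a session manifest).
#'
#' @return `read_session` returns a [session_recording()]; `write_session`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  sig <- session$channels
  fs <- rep(session$fs_signal, length(sig))
  dims <- rep("uV", length(sig))
  if (!is.null(session$position)) {
    sig$pos_x <- session$position[, 1]
    sig$pos_y <- session$position[, 2]
    fs <- c(fs, session$fs_position, session$fs_position)
    dims <- c(dims, "cm", "cm")
  }
  write_edf(path, sig, fs = fs, phys_dim = dims,
            patient = paste(session$mouse_id, session$genotype),
            recording = sprintf("age_weeks=%g", session$age_weeks))
}

#' @rdname write_session
#' @export
read_session <- function(path, mouse_id, genotype, age_weeks) {
  edf <- read_edf(path)
  required <- c("frontal_eeg", "hippocampus_lfp", "emg")
  missing_ch <- setdiff(required, names(edf$signals))
  if (length(missing_ch))
    stop_betasleep(paste0("EDF lacks required channel(s): ",
                          paste(missing_ch, collapse = ", ")),
                   "betasleep_missing_channel")
  position <- NULL
  fs_position <- 50
  if (all(c("pos_x", "pos_y") %in% names(edf$signals))) {
    position <- cbind(x = edf$signals$pos_x, y = edf$signals$pos_y)
    fs_position <- edf$fs[["pos_x"]]
  }
  session_recording(
    mouse_id = mouse_id, genotype = genotype, age_weeks = age_weeks,
    channels = edf$signals[required],
    fs_signal = edf$fs[["frontal_eeg"]],
    position = position, fs_position = fs_position,
    duration_s = edf$duration_s)
}
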