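# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed; seed = NULL uses the current
# RNG stream (so callers can compose several simulation steps under one seed).
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Centered moving average of width k samples; windows shrink at the edges so
# the output has the same length as the input.
moving_average <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k <= 1L || n == 0L) return(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

stop_betasleep <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "betasleep_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

# Polynomial rolling hash (mod 2^31 - 1) of an R object's deparsed form;
# used to stamp output files so runs with different configurations are
# distinguishable.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# CSV writer/reader with '#'-prefixed comment header lines.
write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_commented <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

check_band <- function(band, freqs, what = "band") {
  if (length(band) != 2L || !is.numeric(band) || band[1] >= band[2])
    stop_betasleep(sprintf("%s must be an increasing (lo, hi) pair", what),
                   "betasleep_range_error")
  if (band[1] > max(freqs) || band[2] < min(freqs))
    stop_betasleep(sprintf("%s [%g, %g] lies outside the frequency axis",
                           what, band[1], band[2]),
                   "betasleep_range_error")
  if (!any(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9))
    stop_betasleep(sprintf("no frequency bins inside %s [%g, %g]",
                           what, band[1], band[2]),
                   "betasleep_range_error")
  invisible(band)
}

band_mask <- function(freqs, band) {
  freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
}
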