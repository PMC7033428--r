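# Minimal EDF (European Data Format) writer/reader for continuous EEG.
# EDF stores an ASCII header followed by 16-bit little-endian samples,
# scaled per channel between a physical and a digital range; the
# round-trip quantization error is bounded by (physical range)/65535.
# No R package in our dependency set reads EDF, so the subset needed
# here (one continuous multichannel signal, equal rates) is implemented
# directly against the format definition.

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  digits <- 7
  while (nchar(s) > width && digits > 1) {
    digits <- digits - 1
    s <- formatC(x, format = "g", digits = digits, width = 1)
  }
  if (nchar(s) > width) stop("cannot format ", x, " in ", width, " chars")
  formatC(s, width = width, flag = "-")
}

edf_str <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records; requires an integer sampling
#' rate and a whole number of seconds of data. Physical ranges are taken
#' per channel from the data (so quantization error is far below 1 LSB of
#' typical acquisition hardware).
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param path Output path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  if (n %% fs != 0)
    stop("EDF export requires a whole number of seconds (", n,
         " samples at ", fs, " Hz); use CSV for arbitrary lengths")
  n_rec <- n %/% fs
  ns <- nrow(rec$data)

  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  gain <- (pmax - pmin) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_str("0", 8),
    edf_str("X X X X", 80),
    edf_str("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    edf_num(256L * (1L + ns), 8),
    edf_str("", 44),
    edf_num(n_rec, 8),
    edf_num(1L, 8),
    edf_num(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, edf_str, "", width = 16), collapse = ""),
    paste(rep(edf_str("", 80), ns), collapse = ""),
    paste(rep(edf_str("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, ""), collapse = ""),
    paste(vapply(pmax, edf_num, ""), collapse = ""),
    paste(rep(edf_num(dmin), ns), collapse = ""),
    paste(rep(edf_num(dmax), ns), collapse = ""),
    paste(rep(edf_str("", 80), ns), collapse = ""),
    paste(rep(edf_num(fs), ns), collapse = ""),
    paste(rep(edf_str("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  dig <- matrix(0L, nrow = ns, ncol = n)
  for (i in seq_len(ns)) {
    d <- round((rec$data[i, ] - pmin[i]) / gain[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[i, cols], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports continuous EDF with a common sampling rate across signals;
#' values are rescaled to physical units (assumed microvolts).
#'
#' @param path Path to the EDF file.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) < 256) stop("not an EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("invalid EDF signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8)  # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80) # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  gain <- (pmax - pmin) / (dmax - dmin)

  dat <- matrix(NA_real_, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (i in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[i], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[i]) stop("EDF file truncated in record ", r)
      dat[i, cols] <- (raw - dmin[i]) * gain[i] + pmin[i]
    }
  }
  eeg_recording(dat, fs = fs, channel_labels = labels)
}
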