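# Recording / event-table containers and file IO (long-form CSV and EDF),
# plus cue-aligned epoch extraction.

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples, values in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of \code{data}.
#' @param start_time_s Recording start time in seconds (default 0).
#'
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, fs, channel_labels, start_time_s = 0) {
  data <- as.matrix(data)
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") does not match number of data rows (", nrow(data), ")")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (anyNA(data)) stop("recording contains NaN/NA values")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels),
                 start_time_s = as.numeric(start_time_s)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct an event table
#'
#' One row per trial with the cue-onset and response timestamps; the
#' response delay is their difference and must be positive.
#'
#' @param cue_onset_s Cue-onset times in seconds, strictly increasing.
#' @param response_s Response times in seconds.
#' @param trial Optional integer trial ids (default 1..n).
#'
#' @return A data.frame of class \code{event_table} with columns
#'   \code{trial}, \code{cue_onset_s}, \code{response_s}, \code{delay_s}.
#' @export
event_table <- function(cue_onset_s, response_s, trial = seq_along(cue_onset_s)) {
  if (length(cue_onset_s) != length(response_s))
    stop("cue_onset_s and response_s must have equal length")
  if (is.unsorted(cue_onset_s, strictly = TRUE))
    stop("cue_onset_s must be strictly increasing")
  delay <- response_s - cue_onset_s
  if (any(delay <= 0))
    stop("non-positive response delay at trial(s): ",
         paste(trial[delay <= 0], collapse = ", "))
  structure(data.frame(trial = as.integer(trial),
                       cue_onset_s = as.numeric(cue_onset_s),
                       response_s = as.numeric(response_s),
                       delay_s = as.numeric(delay)),
            class = c("event_table", "data.frame"))
}

#' Write / read an event table as CSV
#'
#' Columns \code{trial,cue_onset_s,response_s} at full double precision;
#' \code{delay_s} is recomputed on load.
#'
#' @param events An \code{\link{event_table}}.
#' @param path Output CSV path.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  data.table::fwrite(events[, c("trial", "cue_onset_s", "response_s")],
                     path)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("trial", "cue_onset_s", "response_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table missing column(s): ", paste(miss, collapse = ", "))
  event_table(df$cue_onset_s, df$response_s, trial = df$trial)
}

#' Write a recording to disk
#'
#' Long-form CSV (\code{time_s} column plus one column per channel, values
#' in microvolts, lossless) or 16-bit EDF (European Data Format; quantized
#' to the per-channel physical range, worst-case error range/65535).
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"edf"}.
#' @export
write_recording <- function(rec, path, format = c("csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "csv") {
    n <- ncol(rec$data)
    df <- data.frame(time_s = rec$start_time_s + (seq_len(n) - 1) / rec$fs)
    for (i in seq_along(rec$channel_labels))
      df[[rec$channel_labels[i]]] <- rec$data[i, ]
    data.table::fwrite(df, path)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Load a recording from disk
#'
#' @param path Path to a CSV (columns \code{time_s} + channels) or EDF file.
#' @param format \code{"csv"} or \code{"edf"}.
#' @param channels Optional required montage; an error names any channel
#'   absent from the file. Channel order is kept as stored.
#'
#' @return An \code{\link{eeg_recording}} in microvolts. For CSV the
#'   sampling rate is inferred from the time column and sampling must be
#'   regular (relative jitter <= 1e-6).
#' @export
load_recording <- function(path, format = c("csv", "edf"), channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (format == "csv") {
    df <- data.table::fread(path, data.table = FALSE)
    if (!"time_s" %in% names(df) || ncol(df) < 2 || nrow(df) < 2)
      stop("recording CSV needs a 'time_s' column, >= 1 channel column and >= 2 rows")
    t <- df$time_s
    dt <- diff(t)
    mdt <- mean(dt)
    if (mdt <= 0 || max(abs(dt - mdt)) / mdt > 1e-6)
      stop("irregular sampling in time column (relative jitter > 1e-6)")
    labs <- setdiff(names(df), "time_s")
    dat <- t(as.matrix(df[, labs, drop = FALSE]))
    rec <- eeg_recording(dat, fs = 1 / mdt, channel_labels = labs,
                         start_time_s = t[1])
  } else {
    rec <- read_edf(path)
  }
  if (!is.null(channels)) {
    miss <- setdiff(channels, rec$channel_labels)
    if (length(miss))
      stop("recording is missing required channel(s): ",
           paste(miss, collapse = ", "))
  }
  rec
}

#' Extract pre-cue epochs (TSIs)
#'
#' Cuts, for every trial, the window of \code{tsi_len_samples} samples that
#' immediately precedes the cue onset. The onset time is mapped to the
#' 0-based sample index \code{floor(cue_onset_s * fs)} and the epoch is the
#' half-open sample range \code{[idx - tsi_len, idx)}, so no sample at or
#' after the cue ever enters the window. Trials whose window would start
#' before the recording (or whose cue falls beyond its end) are dropped and
#' reported.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param events An \code{\link{event_table}}.
#' @param tsi_len_samples Window length in samples (>= 2; 64 corresponds to
#'   0.5 s at 128 Hz).
#'
#' @return An \code{epoch_set}: array \code{trials x channels x samples},
#'   trial ids, ids of dropped trials, and an (initially all-FALSE)
#'   artifact \code{rejected_mask}.
#' @export
extract_tsi <- function(rec, events, tsi_len_samples = 64L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(events, "event_table"))
  tsi_len_samples <- as.integer(tsi_len_samples)
  if (tsi_len_samples < 2L) stop("tsi_len_samples must be >= 2")
  n_samples <- ncol(rec$data)
  # small additive guard against representation error in t * fs
  idx <- floor((events$cue_onset_s - rec$start_time_s) * rec$fs + 1e-9)
  usable <- idx >= tsi_len_samples & idx <= n_samples
  dropped <- events$trial[!usable]
  if (!any(usable))
    stop("no usable trials: every TSI window falls outside the recording")
  keep <- which(usable)
  epochs <- array(NA_real_,
                  dim = c(length(keep), nrow(rec$data), tsi_len_samples),
                  dimnames = list(NULL, rec$channel_labels, NULL))
  for (j in seq_along(keep)) {
    i0 <- idx[keep[j]] # 0-based index of the cue sample
    epochs[j, , ] <- rec$data[, (i0 - tsi_len_samples + 1):i0, drop = FALSE]
  }
  structure(list(
    epochs = epochs,
    n_tsi = tsi_len_samples,
    fs = rec$fs,
    channel_labels = rec$channel_labels,
    trial_ids = events$trial[keep],
    dropped_trials = dropped,
    rejected_mask = rep(FALSE, length(keep))
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d trials x %d channels x %d samples @ %g Hz; %d dropped>\n",
              dim(x$epochs)[1], dim(x$epochs)[2], x$n_tsi, x$fs,
              length(x$dropped_trials)))
  invisible(x)
}

#' Flag high-amplitude artifact epochs
#'
#' An epoch is flagged when its peak-to-peak amplitude on any channel
#' exceeds \code{k} times the median peak-to-peak amplitude of that channel
#' across all epochs. Flagging is report-only: by default all epochs are
#' kept, and removal is the caller's choice.
#'
#' @param epochs An \code{epoch_set} with at least 3 epochs.
#' @param k Amplitude ratio threshold (default 5; \code{Inf} flags nothing).
#'
#' @return Logical vector, one entry per epoch.
#' @export
flag_artifact_epochs <- function(epochs, k = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_trials <- dim(epochs$epochs)[1]
  if (n_trials < 3L) stop("need at least 3 epochs to flag artifacts")
  # peak-to-peak per trial x channel
  ptp <- apply(epochs$epochs, c(1, 2), function(v) max(v) - min(v))
  med <- apply(ptp, 2, stats::median)
  flagged <- vapply(seq_len(n_trials),
                    function(i) any(ptp[i, ] > k * med),
                    logical(1))
  flagged
}

#' Export / import an epoch set as CSV + JSON sidecar
#'
#' The 3-D epoch array is flattened to a CSV with one row per
#' (trial, channel) and one column per sample; the sidecar records trial
#' ids, channel labels, window length and sampling rate.
#'
#' @param epochs An \code{epoch_set}.
#' @param prefix Output path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  flat <- matrix(aperm(epochs$epochs, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  df <- data.frame(trial = rep(epochs$trial_ids, each = d[2]),
                   channel = rep(epochs$channel_labels, times = d[1]))
  df <- cbind(df, as.data.frame(flat))
  data.table::fwrite(df, paste0(prefix, ".csv"))
  meta <- list(trial_ids = epochs$trial_ids,
               channel_labels = epochs$channel_labels,
               n_tsi = d[3], fs = epochs$fs,
               dropped_trials = epochs$dropped_trials,
               rejected_mask = epochs$rejected_mask)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  df <- data.table::fread(paste0(prefix, ".csv"), data.table = FALSE)
  n_trials <- length(meta$trial_ids)
  n_chan <- length(meta$channel_labels)
  flat <- as.matrix(df[, -(1:2), drop = FALSE])
  epochs <- aperm(array(t(flat), dim = c(meta$n_tsi, n_chan, n_trials)),
                  c(3, 2, 1))
  dimnames(epochs) <- list(NULL, meta$channel_labels, NULL)
  structure(list(epochs = epochs, n_tsi = meta$n_tsi, fs = meta$fs,
                 channel_labels = meta$channel_labels,
                 trial_ids = meta$trial_ids,
                 dropped_trials = meta$dropped_trials,
                 rejected_mask = meta$rejected_mask),
            class = "epoch_set")
}
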