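# Zero-padded FFT bandpass filtering of short pre-cue EEG segments.
#
# A 0.5 s segment at 128 Hz is only 64 samples; a direct FFT would give
# 2 Hz bins, too coarse for 4 Hz wide bands. Padding the demeaned segment
# with zeros to 256 samples refines the bin spacing to 0.5 Hz without
# adding information; out-of-band Fourier amplitudes are set to zero and
# the band-limited signal is recovered by the inverse transform.

#' FFT bandpass filter with zero padding
#'
#' Removes the segment mean, appends zeros up to \code{pad_to} samples,
#' takes the FFT, zeroes every bin whose frequency magnitude falls outside
#' the half-open interval \code{[f_low, f_high)} (the DC bin is always
#' zeroed; negative frequencies are masked symmetrically so the inverse is
#' real), inverse-transforms, and returns the first \code{length(x)}
#' samples so the output never describes the padding.
#'
#' @param x Numeric signal (one channel of one epoch), length >= 2.
#' @param fs Sampling rate in Hz.
#' @param band A \code{\link{band_spec}}.
#' @param pad_to Total FFT length after zero padding; must be
#'   >= \code{length(x)}. Default 256 (i.e. 192 zeros for a 64-sample
#'   segment, giving \code{fs / pad_to} = 0.5 Hz bins at 128 Hz).
#'
#' @return Band-limited real signal of the same length as \code{x}.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:63) / 128)
#' y <- fft_bandpass(x, 128, band_spec("Alpha", 8, 12))
fft_bandpass <- function(x, fs, band, pad_to = 256L) {
  n <- length(x)
  if (n < 2L) stop("signal must have at least 2 samples")
  if (!inherits(band, "band_spec")) stop("'band' must be a band_spec")
  if (band$f_low >= fs / 2)
    stop("band '", band$name, "' lies entirely above the Nyquist frequency ",
         fs / 2, " Hz")
  if (pad_to < n) stop("pad_to (", pad_to, ") must be >= signal length ", n)
  if (anyNA(x)) stop("signal contains NA values")

  xp <- c(x - mean(x), numeric(pad_to - n))
  X <- stats::fft(xp)

  k <- seq_len(pad_to) - 1L
  freq <- ifelse(k <= pad_to / 2, k, k - pad_to) * fs / pad_to
  keep <- abs(freq) >= band$f_low & abs(freq) < band$f_high
  keep[1L] <- FALSE # DC always discarded
  X[!keep] <- 0 + 0i

  y <- stats::fft(X, inverse = TRUE) / pad_to
  scale <- max(abs(y), .Machine$double.eps)
  if (max(abs(Im(y))) / scale > 1e-9)
    stop("internal error: inverse transform is not real (asymmetric mask)")
  Re(y)[seq_len(n)]
}

#' Decompose epochs into band-limited signals
#'
#' Applies \code{\link{fft_bandpass}} independently to every
#' trial x channel x band combination of an epoch set.
#'
#' @param epochs An \code{epoch_set} from \code{\link{extract_tsi}}.
#' @param bank List of \code{\link{band_spec}} objects; default the
#'   10-band bank of \code{\link{default_band_bank}}.
#' @param pad_to Total FFT length (default 256).
#'
#' @return A \code{band_signal_set}: a 4-D array
#'   (trial x channel x band x sample) plus metadata (\code{fs},
#'   \code{pad_to}, \code{n_pad_zeros}, frequency resolution).
#' @export
decompose_epochs <- function(epochs, bank = default_band_bank(),
                             pad_to = 256L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(bank) == 0L) stop("band bank is empty")
  n_trials <- dim(epochs$epochs)[1]
  n_chan <- dim(epochs$epochs)[2]
  n_tsi <- dim(epochs$epochs)[3]

  band_names <- vapply(bank, function(b) b$name, character(1))
  out <- array(NA_real_,
               dim = c(n_trials, n_chan, length(bank), n_tsi),
               dimnames = list(NULL, epochs$channel_labels, band_names, NULL))
  for (b in seq_along(bank)) {
    for (ch in seq_len(n_chan)) {
      for (tr in seq_len(n_trials)) {
        out[tr, ch, b, ] <- tryCatch(
          fft_bandpass(epochs$epochs[tr, ch, ], epochs$fs, bank[[b]], pad_to),
          error = function(e) stop("band '", band_names[b], "', channel '",
                                   epochs$channel_labels[ch], "', trial ",
                                   epochs$trial_ids[tr], ": ",
                                   conditionMessage(e), call. = FALSE))
      }
    }
  }
  structure(list(
    signals = out,
    bank = bank,
    channel_labels = epochs$channel_labels,
    trial_ids = epochs$trial_ids,
    fs = epochs$fs,
    pad_to = as.integer(pad_to),
    n_pad_zeros = as.integer(pad_to - n_tsi),
    freq_resolution_hz = epochs$fs / pad_to
  ), class = "band_signal_set")
}

#' @export
print.band_signal_set <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf(
    "<band_signal_set: %d trials x %d channels x %d bands x %d samples; %g Hz bins>\n",
    d[1], d[2], d[3], d[4], x$freq_resolution_hz))
  invisible(x)
}
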