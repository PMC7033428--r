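# Frequency band definitions used throughout the pipeline.

#' Define a frequency band
#'
#' A band is a half-open frequency interval \code{[f_low, f_high)} in Hz.
#' Half-open intervals mean that bands sharing an edge (e.g. Theta 4--8 and
#' Alpha 8--12) never double-count a Fourier bin that falls exactly on the
#' shared edge.
#'
#' @param name Band label, e.g. \code{"Alpha"}.
#' @param f_low Lower edge in Hz (inclusive). Must be > 0.
#' @param f_high Upper edge in Hz (exclusive). Must be > \code{f_low}.
#'
#' @return An object of class \code{band_spec}.
#' @export
#' @examples
#' band_spec("Alpha", 8, 12)
band_spec <- function(name, f_low, f_high) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      !is.finite(f_low) || !is.finite(f_high) ||
      f_low <= 0 || f_high <= f_low) {
    stop("band '", name, "': need 0 < f_low < f_high (got [",
         f_low, ", ", f_high, "))")
  }
  structure(list(name = name, f_low = as.numeric(f_low),
                 f_high = as.numeric(f_high)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: [%g, %g) Hz>\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

#' Default 10-band EEG bank
#'
#' The classical brainwave decomposition used for bandpower features:
#' Delta 1--4, Theta 4--8, Alpha 8--12, LowBeta 12--16, MidBeta 16--20,
#' MidHighBeta 20--24, HighBeta 24--28, Gamma1 32--36, Gamma2 36--40 Hz,
#' plus a Broad 8--30 Hz sensorimotor range. The 28--32 Hz gap between
#' HighBeta and Gamma1 is intentional.
#'
#' @return A named list of \code{\link{band_spec}} objects.
#' @export
default_band_bank <- function() {
  bands <- list(
    band_spec("Delta",       1, 4),
    band_spec("Theta",       4, 8),
    band_spec("Alpha",       8, 12),
    band_spec("LowBeta",    12, 16),
    band_spec("MidBeta",    16, 20),
    band_spec("MidHighBeta", 20, 24),
    band_spec("HighBeta",   24, 28),
    band_spec("Gamma1",     32, 36),
    band_spec("Gamma2",     36, 40),
    band_spec("Broad",       8, 30)
  )
  names(bands) <- vapply(bands, function(b) b$name, character(1))
  bands
}

#' Read a band bank from a YAML file
#'
#' The file holds a list of entries with fields \code{name}, \code{low},
#' \code{high} (Hz).
#'
#' @param path Path to the YAML file.
#' @return A named list of \code{\link{band_spec}} objects.
#' @export
read_band_bank <- function(path) {
  spec <- yaml::read_yaml(path)
  bands <- lapply(spec, function(b) {
    if (is.null(b$name) || is.null(b$low) || is.null(b$high))
      stop("band bank entries need fields 'name', 'low', 'high'")
    band_spec(b$name, b$low, b$high)
  })
  names(bands) <- vapply(bands, function(b) b$name, character(1))
  bands
}

#' Default 14-channel montage
#'
#' Channel labels of the 14-electrode 10-10 subset used by consumer EEG
#' headsets (AF3 ... AF4 ordering).
#'
#' @return Character vector of 14 channel labels.
#' @export
default_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}
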