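# Synthetic flight-simulator EEG sessions: a cue schedule with normally
# distributed inter-arrival times, 14-channel EEG built from band-limited
# oscillations plus 1/f noise, and reaction delays generated from a
# configurable linear model on the planted band-power (logvar) of the
# pre-cue window. The generator carries its ground truth so the whole
# downstream pipeline can be tested for signal recovery.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Configuration of a simulated experiment session
#'
#' Defaults emulate a ~2 h recording session: visual cues arrive with
#' normally distributed inter-arrival times (mean 150 s, sd 60 s,
#' truncated below at \code{min_gap_s}), 14 channels sampled at 128 Hz,
#' and reaction delays around 0.55 s floored at 0.25 s.
#'
#' @param session_length_s Session length in seconds (default 7200).
#' @param fs Sampling rate in Hz (default 128).
#' @param channel_labels Montage (default \code{\link{default_montage}}).
#' @param band_bank Band definitions used to plant oscillations (default
#'   \code{\link{default_band_bank}}).
#' @param cue_interval_mean_s,cue_interval_sd_s Mean / sd of the normal
#'   inter-cue interval in seconds (defaults 150 and 60).
#' @param min_gap_s Lower truncation bound of the inter-cue interval
#'   (default 10 s; back-to-back cues are physically implausible).
#' @param schedule_margin_s Tail margin in seconds: no cue is scheduled
#'   after \code{session_length_s - tsi_s - schedule_margin_s}, so the
#'   slowest plausible response still falls inside the recording
#'   (default 5).
#' @param tsi_s Pre-cue window length in seconds (default 0.5).
#' @param coupling Named numeric vector mapping planted features to delay
#'   coefficients in seconds per logvar unit; names use the
#'   \code{CHANNEL_Band} convention, e.g. \code{c(O1_Alpha = 0.15)}.
#'   Default empty (no EEG-delay coupling).
#' @param delay_baseline_s,delay_noise_sd_s,delay_floor_s Baseline, noise
#'   sd and hard floor of the generated delays in seconds (defaults 0.55,
#'   0.05, 0.25).
#' @param baseline_amp_uV Oscillation amplitude outside pre-cue windows
#'   (default 2 microvolts).
#' @param amp_meanlog,amp_sdlog Log-normal parameters of the per-trial
#'   planted band amplitudes (defaults \code{log(5)} and 0.6, i.e. a
#'   median of 5 microvolts).
#' @param noise_rms_uV RMS of the additive 1/f (pink) broadband noise
#'   (default 4 microvolts).
#' @param mains_50hz_uV Amplitude of an optional 50 Hz mains tone
#'   (default 0: acquisition hardware notch-filters it).
#' @param seed Base random seed.
#'
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(session_length_s = 7200,
                       fs = 128,
                       channel_labels = default_montage(),
                       band_bank = default_band_bank(),
                       cue_interval_mean_s = 150,
                       cue_interval_sd_s = 60,
                       min_gap_s = 10,
                       schedule_margin_s = 5,
                       tsi_s = 0.5,
                       coupling = numeric(0),
                       delay_baseline_s = 0.55,
                       delay_noise_sd_s = 0.05,
                       delay_floor_s = 0.25,
                       baseline_amp_uV = 2,
                       amp_meanlog = log(5),
                       amp_sdlog = 0.6,
                       noise_rms_uV = 4,
                       mains_50hz_uV = 0,
                       seed = 1L) {
  cfg <- list(session_length_s = session_length_s, fs = fs,
              channel_labels = channel_labels, band_bank = band_bank,
              cue_interval_mean_s = cue_interval_mean_s,
              cue_interval_sd_s = cue_interval_sd_s,
              min_gap_s = min_gap_s, schedule_margin_s = schedule_margin_s,
              tsi_s = tsi_s, coupling = coupling,
              delay_baseline_s = delay_baseline_s,
              delay_noise_sd_s = delay_noise_sd_s,
              delay_floor_s = delay_floor_s,
              baseline_amp_uV = baseline_amp_uV,
              amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
              noise_rms_uV = noise_rms_uV, mains_50hz_uV = mains_50hz_uV,
              seed = as.integer(seed))
  if (session_length_s <= 0 || fs <= 0) stop("session_length_s and fs must be > 0")
  if (!(cue_interval_mean_s > cue_interval_sd_s) || cue_interval_sd_s < 0)
    stop("need cue_interval_mean_s > cue_interval_sd_s >= 0")
  if (delay_floor_s <= 0) stop("delay_floor_s must be > 0")
  if (length(cfg$coupling) && is.null(names(cfg$coupling)))
    stop("coupling must be a named vector (CHANNEL_Band = coefficient)")
  for (nm in names(cfg$coupling)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% channel_labels ||
        !parts[2] %in% names(band_bank))
      stop("coupling name '", nm, "' is not a known CHANNEL_Band pair")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a cue schedule
#'
#' Draws inter-cue intervals from N(mean, sd), resampling any draw below
#' \code{min_gap_s}, and accumulates onsets until the tail margin
#' (\code{tsi_s + schedule_margin_s} before session end) is reached. With
#' the defaults (mean 150 s, sd 60 s, 7200 s session) the expected event
#' count is ~48.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Seed (default \code{config$seed}).
#'
#' @return Numeric vector of strictly increasing cue-onset seconds.
#' @export
simulate_cue_schedule <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$cue_interval_mean_s
  s <- config$cue_interval_sd_s
  if (s > 0 && stats::pnorm(config$min_gap_s, m, s) > 0.5)
    stop("degenerate schedule parameters: truncation at ", config$min_gap_s,
         " s would discard more than half of the N(", m, ", ", s, ") draws")
  horizon <- config$session_length_s - config$tsi_s - config$schedule_margin_s
  with_seed(seed, {
    onsets <- numeric(0)
    t <- 0
    repeat {
      gap <- if (s > 0) {
        g <- stats::rnorm(1, m, s)
        while (g < config$min_gap_s) g <- stats::rnorm(1, m, s)
        g
      } else m
      if (t + gap >= horizon) break
      t <- t + gap
      onsets <- c(onsets, t)
    }
    onsets
  })
}

#' Draw per-trial planted band amplitudes
#'
#' Log-normal amplitudes (microvolts) for every trial x channel x band;
#' log-normality makes the downstream logvar features approximately
#' normal.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_trials Number of trials.
#' @param seed Seed (default \code{config$seed + 1}).
#'
#' @return Array \code{n_trials x channels x bands} with dimnames.
#' @export
simulate_band_amplitudes <- function(config, n_trials,
                                     seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  nc <- length(config$channel_labels)
  nb <- length(config$band_bank)
  with_seed(seed, {
    array(stats::rlnorm(n_trials * nc * nb, config$amp_meanlog,
                        config$amp_sdlog),
          dim = c(n_trials, nc, nb),
          dimnames = list(NULL, config$channel_labels,
                          names(config$band_bank)))
  })
}

# ln(variance) of the planted sinusoidal component with amplitude a:
# a full-cycle sinusoid of amplitude a has variance a^2 / 2.
planted_logvar <- function(a) log(a^2 / 2)

#' Generate reaction delays from planted band powers
#'
#' \code{delay_i = max(floor, baseline + sum_j coupling_j * logvar_ij + e_i)}
#' where \code{logvar_ij} is the log variance of the planted oscillation of
#' coupled feature j in trial i and \code{e_i ~ N(0, delay_noise_sd_s)}.
#'
#' @param schedule Cue onsets (defines the number of trials).
#' @param amplitudes Array from \code{\link{simulate_band_amplitudes}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Seed (default \code{config$seed + 2}).
#'
#' @return Numeric vector of delays in seconds (all >= delay floor).
#' @export
simulate_delays <- function(schedule, amplitudes, config,
                            seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(schedule)
  if (n == 0L) stop("empty schedule")
  if (dim(amplitudes)[1] != n)
    stop("amplitudes have ", dim(amplitudes)[1], " trials, schedule has ", n)
  mu <- rep(config$delay_baseline_s, n)
  for (nm in names(config$coupling)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    mu <- mu + config$coupling[[nm]] *
      planted_logvar(amplitudes[, parts[1], parts[2]])
  }
  with_seed(seed, {
    eps <- if (config$delay_noise_sd_s > 0)
      stats::rnorm(n, 0, config$delay_noise_sd_s) else numeric(n)
    pmax(config$delay_floor_s, mu + eps)
  })
}

# Pink (1/f) noise of length n via spectral shaping, unit RMS.
pink_noise <- function(n) {
  nf <- n %/% 2
  f <- seq_len(nf)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) / sqrt(f)
  if (n %% 2 == 0) spec[nf] <- complex(real = Re(spec[nf]), imaginary = 0)
  full <- c(0 + 0i, spec, Conj(rev(spec[seq_len(nf - (1 - n %% 2))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize a multichannel EEG recording
#'
#' Each channel is a sum over bands of a sinusoid at the band's
#' mid-frequency whose amplitude is \code{baseline_amp_uV} outside pre-cue
#' windows and the trial's planted amplitude inside them, plus 1/f
#' broadband noise scaled to \code{noise_rms_uV} (and an optional 50 Hz
#' mains tone). Phases are random per channel and band.
#'
#' @param config A \code{\link{sim_config}}.
#' @param schedule Cue onsets in seconds.
#' @param amplitudes Array from \code{\link{simulate_band_amplitudes}}.
#' @param seed Seed (default \code{config$seed + 3}).
#'
#' @return An \code{\link{eeg_recording}} of
#'   \code{session_length_s * fs} samples.
#' @export
synthesize_eeg <- function(config, schedule, amplitudes,
                           seed = config$seed + 3L) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  carriers <- vapply(config$band_bank,
                     function(b) (b$f_low + b$f_high) / 2, numeric(1))
  if (any(carriers >= fs / 2))
    stop("band carrier frequency at or above Nyquist: ",
         paste(names(carriers)[carriers >= fs / 2], collapse = ", "))
  n <- as.integer(round(config$session_length_s * fs))
  tt <- (seq_len(n) - 1) / fs
  nc <- length(config$channel_labels)
  nb <- length(config$band_bank)

  # sample index ranges of the pre-cue windows, half-open [on - tsi, on)
  tsi_n <- as.integer(round(config$tsi_s * fs))
  cue_idx <- floor(schedule * fs + 1e-9) # 0-based cue sample
  win <- lapply(cue_idx, function(i0)
    seq.int(max(1L, i0 - tsi_n + 1L), max(1L, i0))) # 1-based rows

  with_seed(seed, {
    phases <- matrix(stats::runif(nc * nb, 0, 2 * pi), nrow = nc)
    dat <- matrix(0, nrow = nc, ncol = n)
    sin_b <- lapply(carriers, function(f) sin(2 * pi * f * tt))
    cos_b <- lapply(carriers, function(f) cos(2 * pi * f * tt))
    for (ch in seq_len(nc)) {
      sig <- numeric(n)
      for (b in seq_len(nb)) {
        env <- rep(config$baseline_amp_uV, n)
        for (i in seq_along(win)) env[win[[i]]] <- amplitudes[i, ch, b]
        sig <- sig + env * (sin_b[[b]] * cos(phases[ch, b]) +
                              cos_b[[b]] * sin(phases[ch, b]))
      }
      if (config$noise_rms_uV > 0)
        sig <- sig + config$noise_rms_uV * pink_noise(n)
      if (config$mains_50hz_uV > 0)
        sig <- sig + config$mains_50hz_uV * sin(2 * pi * 50 * tt)
      dat[ch, ] <- sig
    }
    eeg_recording(dat, fs = fs, channel_labels = config$channel_labels)
  })
}

#' Simulate a complete session
#'
#' Runs schedule, amplitude, delay and EEG generation from one base seed
#' and assembles the event table (responses emitted at
#' \code{cue + delay}, so delays can be recomputed from the events the
#' same way as for real recordings).
#'
#' @param config A \code{\link{sim_config}}.
#'
#' @return A list of class \code{sim_session}: \code{recording},
#'   \code{events}, and \code{ground_truth} (schedule, amplitudes, true
#'   delays, coupling, config).
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- simulate_cue_schedule(config)
  amplitudes <- simulate_band_amplitudes(config, length(schedule))
  delays <- simulate_delays(schedule, amplitudes, config)
  recording <- synthesize_eeg(config, schedule, amplitudes)
  events <- event_table(schedule, schedule + delays)
  structure(list(
    recording = recording,
    events = events,
    ground_truth = list(cue_onsets_s = schedule,
                        amplitudes = amplitudes,
                        true_delays_s = delays,
                        coupling = config$coupling,
                        config = config)
  ), class = "sim_session")
}

#' Write a simulated session to disk
#'
#' Writes \code{recording.csv} (or \code{recording.edf}),
#' \code{events.csv} and \code{ground_truth.json} into a directory.
#'
#' @param session A \code{\link{simulate_session}} result.
#' @param dir Output directory (created if needed).
#' @param format Recording format, \code{"csv"} or \code{"edf"}.
#' @export
write_session <- function(session, dir, format = c("csv", "edf")) {
  stopifnot(inherits(session, "sim_session"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recording(session$recording,
                  file.path(dir, paste0("recording.", format)), format)
  write_event_table(session$events, file.path(dir, "events.csv"))
  gt <- session$ground_truth
  jsonlite::write_json(
    list(cue_onsets_s = gt$cue_onsets_s,
         true_delays_s = gt$true_delays_s,
         coupling = as.list(gt$coupling),
         amplitudes = gt$amplitudes),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}
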