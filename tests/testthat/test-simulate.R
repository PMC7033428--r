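test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(session_length_s = -1), "must be > 0")
  expect_error(sim_config(cue_interval_mean_s = 50, cue_interval_sd_s = 60),
               "cue_interval_mean_s > cue_interval_sd_s")
  expect_error(sim_config(delay_floor_s = 0), "delay_floor_s")
  expect_error(sim_config(coupling = c(NoSuch_Alpha = 0.1)),
               "not a known CHANNEL_Band")
  expect_error(sim_config(coupling = c(O1_Sigma = 0.1)),
               "not a known CHANNEL_Band")
})

test_that("cue schedules have the configured inter-arrival statistics", {
  cfg <- sim_config()
  gaps <- unlist(lapply(1:200, function(s) {
    diff(c(0, simulate_cue_schedule(cfg, seed = s)))
  }))
  expect_lt(abs(mean(gaps) - 150), 5)
  expect_lt(abs(sd(gaps) - 60), 5)
  expect_gte(min(gaps), cfg$min_gap_s)
})

test_that("degenerate schedules: zero sd gives exact multiples of the mean", {
  cfg <- sim_config(cue_interval_sd_s = 0)
  on <- simulate_cue_schedule(cfg)
  expect_equal(on, seq(150, max(on), by = 150))
  expect_lt(max(on), 7200 - 0.5 - 5)
})

test_that("schedules are deterministic given the seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(simulate_cue_schedule(cfg), simulate_cue_schedule(cfg))
  expect_false(identical(simulate_cue_schedule(cfg, seed = 1),
                         simulate_cue_schedule(cfg, seed = 2)))
})

test_that("a truncation that would discard most draws is rejected", {
  cfg <- sim_config(cue_interval_mean_s = 12, cue_interval_sd_s = 10,
                    min_gap_s = 20)
  expect_error(simulate_cue_schedule(cfg), "degenerate")
})

test_that("delays follow the planted linear model on logvar", {
  cfg <- sim_config(coupling = numeric(0), delay_noise_sd_s = 0)
  sched <- seq(10, 100, by = 10)
  amps <- simulate_band_amplitudes(cfg, length(sched))
  expect_equal(simulate_delays(sched, amps, cfg),
               rep(cfg$delay_baseline_s, length(sched)))

  # noise sd recovered by direct simulation (law of large numbers)
  cfg2 <- sim_config(delay_noise_sd_s = 0.05, delay_floor_s = 0.01)
  sched2 <- seq_len(600)
  amps2 <- simulate_band_amplitudes(cfg2, 600)
  d <- simulate_delays(sched2, amps2, cfg2)
  expect_lt(abs(sd(d) - 0.05), 0.01)

  # single coupling: planted logvar correlates strongly with the delay
  cfg3 <- sim_config(coupling = c(O1_Alpha = 0.15), delay_noise_sd_s = 0.01)
  amps3 <- simulate_band_amplitudes(cfg3, 600)
  d3 <- simulate_delays(sched2, amps3, cfg3)
  lv <- log(amps3[, "O1", "Alpha"]^2 / 2)
  expect_gt(cor(lv, d3), 0.8)
})

test_that("delays never fall below the floor", {
  cfg <- sim_config(delay_baseline_s = 0.3, delay_noise_sd_s = 0.3,
                    delay_floor_s = 0.25)
  amps <- simulate_band_amplitudes(cfg, 500)
  d <- simulate_delays(seq_len(500), amps, cfg)
  expect_gte(min(d), 0.25)
})

test_that("synthesized EEG places band power where it was planted", {
  # single 8-12 Hz component at 10 Hz, no noise
  bank <- list(Alpha = band_spec("Alpha", 8, 12))
  cfg <- sim_config(session_length_s = 60, cue_interval_mean_s = 20,
                    cue_interval_sd_s = 0, min_gap_s = 1,
                    band_bank = bank, noise_rms_uV = 0, seed = 3)
  sched <- simulate_cue_schedule(cfg)
  amps <- simulate_band_amplitudes(cfg, length(sched))
  rec <- synthesize_eeg(cfg, sched, amps)
  spec <- Mod(fft(rec$data[1, ]))^2
  freqs <- (seq_along(spec) - 1) / 60 # bin width 1/60 Hz
  peak <- freqs[which.max(spec[freqs <= 64])]
  expect_equal(peak, 10, tolerance = 0.05)

  # doubling the planted TSI amplitude quadruples the in-window variance
  amps2 <- amps
  amps2[, , ] <- 2 * cfg$baseline_amp_uV
  rec2 <- synthesize_eeg(cfg, sched, amps2)
  i0 <- floor(sched[1] * cfg$fs)
  tsi <- (i0 - 63):i0
  base <- (i0 + 130):(i0 + 193) # a window away from any cue
  expect_equal(var(rec2$data[1, tsi]) / var(rec2$data[1, base]), 4,
               tolerance = 0.1)
})

test_that("a carrier at or above Nyquist is rejected", {
  bank <- list(Bad = band_spec("Bad", 60, 70))
  cfg <- sim_config(session_length_s = 60, cue_interval_mean_s = 20,
                    cue_interval_sd_s = 0, min_gap_s = 1, band_bank = bank)
  sched <- simulate_cue_schedule(cfg)
  amps <- simulate_band_amplitudes(cfg, length(sched))
  expect_error(synthesize_eeg(cfg, sched, amps), "Nyquist")
})

test_that("sessions are deterministic and respect their invariants", {
  cfg <- short_sim_config(seed = 21)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$events, s2$events)
  gt <- s1$ground_truth
  expect_false(is.unsorted(gt$cue_onsets_s, strictly = TRUE))
  expect_lt(max(gt$cue_onsets_s), cfg$session_length_s)
  expect_length(gt$true_delays_s, length(gt$cue_onsets_s))
  expect_gte(min(gt$true_delays_s), cfg$delay_floor_s)
  expect_equal(ncol(s1$recording$data), 600 * 128)
})

test_that("a written session round-trips delays through disk", {
  ses <- short_session()
  dir <- withr::local_tempdir()
  write_session(ses, dir, format = "csv")
  rec <- load_recording(file.path(dir, "recording.csv"), "csv",
                        channels = default_montage())
  ev <- read_event_table(file.path(dir, "events.csv"))
  expect_equal(ev$delay_s, ses$ground_truth$true_delays_s,
               tolerance = 1e-9)
  expect_equal(rec$fs, 128, tolerance = 1e-6)
  expect_equal(rec$data, ses$recording$data, ignore_attr = TRUE,
               tolerance = 1e-8)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$true_delays_s, ses$ground_truth$true_delays_s)
})
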