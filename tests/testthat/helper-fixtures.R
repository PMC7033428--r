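# Shared fixtures, generated in code (no data files).

# A short session config: ~14 trials in 10 minutes, cheap to synthesize.
short_sim_config <- function(seed = 5, ...) {
  sim_config(session_length_s = 600, cue_interval_mean_s = 40,
             cue_interval_sd_s = 10, min_gap_s = 5, seed = seed, ...)
}

# Lazily built, memoized sessions (synthesis of a full-length session is
# the expensive step; several tests share one).
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

short_session <- function() cached("short", function() {
  simulate_session(short_sim_config())
})

# Full-length session with one planted coupling (O1 alpha power -> delay).
coupled_session <- function() cached("coupled", function() {
  simulate_session(sim_config(seed = 11, coupling = c(O1_Alpha = 0.2)))
})

session_features <- function(ses, tsi_len = 64L) {
  ep <- extract_tsi(ses$recording, ses$events, tsi_len)
  build_feature_matrix(decompose_epochs(ep), ses$events)
}

# Compact SVR grid for protocol-level tests where grid breadth is not the
# property under test.
small_svr_spec <- function(algorithm = "svr_rbf") {
  model_spec(algorithm,
             grid = list(C = c(1, 10), gamma = c(0.01, 0.1), epsilon = 0.05),
             k_grid = c(10, 140))
}

# A tiny deterministic recording: one linear-ramp channel (values = 0-based
# sample index), handy for indexing checks.
ramp_recording <- function(n = 256, fs = 128, n_chan = 1) {
  eeg_recording(matrix(rep(0:(n - 1), each = n_chan), nrow = n_chan),
                fs = fs, channel_labels = paste0("CH", seq_len(n_chan)))
}
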