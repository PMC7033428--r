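# End-to-end orchestration: recording + events -> epochs -> band signals
# -> logvar features -> repeated-split evaluation -> statistical reports,
# with a provenance manifest so a run can be reproduced exactly.

#' Assemble a pipeline run configuration
#'
#' @param recording Path to the recording file.
#' @param events Path to the event-table CSV.
#' @param format Recording format, \code{"csv"} or \code{"edf"}.
#' @param tsi_seconds Pre-cue window length in seconds (default 0.5);
#'   \code{tsi_seconds * fs} must be an integer sample count.
#' @param pad_to FFT length after zero padding (default 256).
#' @param band_bank Band definitions (default \code{\link{default_band_bank}}).
#' @param montage Required channel labels (default
#'   \code{\link{default_montage}}); set \code{NULL} to accept any.
#' @param artifact_k Peak-to-peak ratio for artifact flagging (default 5);
#'   flagged epochs are reported, and dropped only when
#'   \code{drop_artifacts} is TRUE (default FALSE: all epochs kept).
#' @param drop_artifacts Remove flagged epochs before feature extraction.
#' @param specs List of \code{\link{model_spec}}s to evaluate.
#' @param scheme A \code{\link{split_scheme}}.
#'
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(recording, events, format = c("csv", "edf"),
                       tsi_seconds = 0.5, pad_to = 256L,
                       band_bank = default_band_bank(),
                       montage = default_montage(),
                       artifact_k = 5, drop_artifacts = FALSE,
                       specs = list(model_spec("lasso"),
                                    model_spec("lasso_lars"),
                                    model_spec("kernel_ridge_rbf"),
                                    model_spec("svr_rbf"),
                                    model_spec("shuffled_svr_rbf")),
                       scheme = split_scheme()) {
  format <- match.arg(format)
  structure(list(recording = recording, events = events, format = format,
                 tsi_seconds = tsi_seconds, pad_to = as.integer(pad_to),
                 band_bank = band_bank, montage = montage,
                 artifact_k = artifact_k, drop_artifacts = drop_artifacts,
                 specs = specs, scheme = scheme),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: \code{recording}, \code{events}, \code{format},
#' \code{tsi_seconds}, \code{pad_to}, \code{bands} (list of
#' name/low/high), \code{montage}, \code{artifact_k},
#' \code{drop_artifacts}, \code{models} (list of algorithm/grid/k_grid),
#' \code{repetitions}, \code{train_fraction}, \code{cv_folds},
#' \code{seed}. Missing keys fall back to the \code{\link{run_config}}
#' defaults.
#'
#' @param path Path to the YAML file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$recording) || is.null(cfg$events))
    stop("run config must name 'recording' and 'events' paths")
  args <- list(recording = cfg$recording, events = cfg$events)
  if (!is.null(cfg$format)) args$format <- cfg$format
  if (!is.null(cfg$tsi_seconds)) args$tsi_seconds <- cfg$tsi_seconds
  if (!is.null(cfg$pad_to)) args$pad_to <- cfg$pad_to
  if (!is.null(cfg$bands)) {
    bands <- lapply(cfg$bands, function(b) band_spec(b$name, b$low, b$high))
    names(bands) <- vapply(bands, function(b) b$name, character(1))
    args$band_bank <- bands
  }
  if (!is.null(cfg$montage)) args$montage <- cfg$montage
  if (!is.null(cfg$artifact_k)) args$artifact_k <- cfg$artifact_k
  if (!is.null(cfg$drop_artifacts)) args$drop_artifacts <- cfg$drop_artifacts
  if (!is.null(cfg$models))
    args$specs <- lapply(cfg$models, function(m)
      model_spec(m$algorithm, grid = m$grid, k_grid = m$k_grid))
  args$scheme <- split_scheme(
    n_repetitions = cfg$repetitions %||% 11L,
    train_fraction = cfg$train_fraction %||% 0.75,
    inner_cv_folds = cfg$cv_folds %||% 3L,
    base_seed = cfg$seed %||% 1L)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in order: load recording and events, cut pre-cue epochs, flag
#' (optionally drop) artifact epochs, decompose into bands, build logvar
#' features, evaluate the configured models under the repeated-split
#' protocol, and compute the statistical reports (delay summary, one-way
#' ANOVA and pairwise t-tests across algorithms' absolute errors,
#' selected-feature counts). All outputs plus a provenance manifest are
#' written to \code{out_dir}; a rerun with the same config and seed
#' reproduces \code{results.json} exactly.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with \code{features}, \code{result},
#'   \code{stats} and \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr),
                    error = function(e) stop("stage '", name, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
    message(sprintf("[eegrt] %-10s %6.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  rec <- stage("load", load_recording(config$recording, config$format,
                                      channels = config$montage))
  events <- stage("events", read_event_table(config$events))
  n_tsi <- config$tsi_seconds * rec$fs
  if (abs(n_tsi - round(n_tsi)) > 1e-9)
    stop("tsi_seconds * fs = ", n_tsi, " is not an integer sample count")
  n_tsi <- as.integer(round(n_tsi))
  if (config$pad_to < n_tsi)
    stop("pad_to (", config$pad_to, ") smaller than the TSI length ", n_tsi)

  epochs <- stage("epoch", extract_tsi(rec, events, n_tsi))
  epochs$rejected_mask <- stage("artifacts",
                                flag_artifact_epochs(epochs, config$artifact_k))
  kept_events <- events[events$trial %in% epochs$trial_ids, ]
  if (config$drop_artifacts && any(epochs$rejected_mask)) {
    keep <- !epochs$rejected_mask
    epochs$epochs <- epochs$epochs[keep, , , drop = FALSE]
    epochs$trial_ids <- epochs$trial_ids[keep]
    epochs$rejected_mask <- epochs$rejected_mask[keep]
  }

  bands <- stage("decompose",
                 decompose_epochs(epochs, config$band_bank, config$pad_to))
  fm <- stage("features", build_feature_matrix(bands, events))
  result <- stage("evaluate", evaluate_subject(fm, config$specs, config$scheme))

  stats_rep <- stage("stats", {
    ae_groups <- lapply(result$algorithms, function(a)
      unlist(lapply(a$repetitions, `[[`, "ae")))
    anova <- if (length(ae_groups) >= 2) anova_oneway(ae_groups) else NULL
    ttests <- if (length(ae_groups) >= 2) pairwise_ttests(ae_groups) else NULL
    list(delay_summary = summarize_delays(kept_events),
         anova = anova, ttests = ttests,
         selected = summarize_selected_features(result))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegrt")),
    recording = config$recording, events = config$events,
    format = config$format,
    fs_hz = rec$fs, n_tsi = n_tsi,
    n_pad_zeros = config$pad_to - n_tsi, fft_length = config$pad_to,
    bands = lapply(unname(config$band_bank),
                   function(b) list(name = b$name, low = b$f_low,
                                    high = b$f_high)),
    montage = rec$channel_labels,
    artifact_k = config$artifact_k, drop_artifacts = config$drop_artifacts,
    n_flagged = sum(epochs$rejected_mask),
    dropped_trials = epochs$dropped_trials,
    n_trials = length(epochs$trial_ids),
    scheme = unclass(config$scheme),
    algorithms = vapply(config$specs, function(s) s$algorithm, character(1)))

  # serializable results: per-repetition AEs, chosen params, selections
  results_json <- list(
    aggregates = result$aggregates,
    repetitions = lapply(result$algorithms, function(a)
      lapply(a$repetitions, function(r)
        list(seed = r$seed, ae = r$ae, params = r$params,
             k = r$k %||% NULL, selected = r$selected))))

  write_feature_matrix(fm, file.path(out_dir, "features.csv"))
  jsonlite::write_json(results_json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$aggregates,
                   file.path(out_dir, "mae_by_algorithm.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_rep$delay_summary,
                   file.path(out_dir, "delay_summary.csv"), row.names = FALSE)
  if (!is.null(stats_rep$ttests))
    utils::write.csv(as.data.frame(stats_rep$ttests),
                     file.path(out_dir, "pairwise_ttests.csv"))
  if (!is.null(stats_rep$anova))
    jsonlite::write_json(stats_rep$anova,
                         file.path(out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA)
  utils::write.csv(stats_rep$selected$pooled,
                   file.path(out_dir, "selected_features.csv"),
                   row.names = FALSE)

  invisible(list(features = fm, result = result, stats = stats_rep,
                 manifest = manifest))
}
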