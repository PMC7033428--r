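# Log-variance bandpower features and train-only standardization.

#' Log-variance bandpower of a band-limited signal
#'
#' A bandpass-filtered signal has near-zero mean, so its variance measures
#' the band power; the natural log makes the feature distribution
#' approximately normal. Variance uses the population (1/N) convention —
#' the choice cancels after standardization.
#'
#' @param x Band-limited numeric signal, length >= 2.
#'
#' @return \code{ln(var(x))} (one number).
#' @export
#' @examples
#' logvar(sin(2 * pi * (0:63) / 8)) # unit sinusoid: ln(1/2)
logvar <- function(x) {
  if (length(x) < 2L) stop("logvar needs at least 2 samples")
  v <- mean((x - mean(x))^2)
  if (v <= 0) stop("zero-variance signal (dead channel or all-zero band)")
  log(v)
}

#' Build the trial x feature logvar matrix
#'
#' One column per (channel, band) pair, channels in montage order outer,
#' bands in bank order inner, labelled \code{CHANNEL_Band}
#' (e.g. \code{AF3_Gamma1}). With 14 channels and 10 bands this yields the
#' 140-feature layout. The target vector is the per-trial response delay,
#' aligned by trial id.
#'
#' @param bands A \code{band_signal_set} from \code{\link{decompose_epochs}}.
#' @param events An \code{\link{event_table}} covering the same trials.
#'
#' @return A \code{feature_matrix}: list with \code{values}
#'   (trials x features), \code{column_labels}, \code{y} (delay_s) and
#'   \code{trial_ids}.
#' @export
build_feature_matrix <- function(bands, events) {
  stopifnot(inherits(bands, "band_signal_set"), inherits(events, "event_table"))
  miss <- setdiff(bands$trial_ids, events$trial)
  if (length(miss))
    stop("trials present in band signals but not in events: ",
         paste(miss, collapse = ", "))
  d <- dim(bands$signals)
  n_trials <- d[1]; n_chan <- d[2]; n_bands <- d[3]
  band_names <- vapply(bands$bank, function(b) b$name, character(1))
  labels <- as.vector(t(outer(bands$channel_labels, band_names, paste, sep = "_")))
  vals <- matrix(NA_real_, nrow = n_trials, ncol = n_chan * n_bands,
                 dimnames = list(NULL, labels))
  for (ch in seq_len(n_chan)) {
    for (b in seq_len(n_bands)) {
      col <- (ch - 1L) * n_bands + b
      for (tr in seq_len(n_trials)) {
        vals[tr, col] <- tryCatch(
          logvar(bands$signals[tr, ch, b, ]),
          error = function(e) stop("trial ", bands$trial_ids[tr],
                                   ", feature ", labels[col], ": ",
                                   conditionMessage(e), call. = FALSE))
      }
    }
  }
  if (any(!is.finite(vals))) stop("non-finite feature values produced")
  y <- events$delay_s[match(bands$trial_ids, events$trial)]
  structure(list(values = vals, column_labels = labels, y = y,
                 trial_ids = bands$trial_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d trials x %d features>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Fit / apply a column standardizer
#'
#' Per-column mean and population standard deviation are learned from the
#' training rows only and applied unchanged to any rows, so no test-set
#' statistics ever leak into training.
#'
#' @param fm A \code{\link{build_feature_matrix}} result.
#' @param train_idx Row indices of the training subset (>= 2 rows).
#'
#' @return A \code{standardizer} (fit) or a transformed
#'   \code{feature_matrix} (apply).
#' @export
fit_standardizer <- function(fm, train_idx) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(train_idx) < 2L) stop("need at least 2 training rows")
  tr <- fm$values[train_idx, , drop = FALSE]
  mu <- colMeans(tr)
  sigma <- sqrt(colMeans(sweep(tr, 2, mu)^2)) # population sd
  bad <- sigma <= 0
  if (any(bad))
    stop("zero standard deviation in training column(s): ",
         paste(fm$column_labels[bad], collapse = ", "))
  structure(list(mean = mu, sd = sigma, column_labels = fm$column_labels),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted \code{standardizer}.
#' @export
apply_standardizer <- function(std, fm) {
  stopifnot(inherits(std, "standardizer"), inherits(fm, "feature_matrix"))
  if (!identical(std$column_labels, fm$column_labels))
    stop("standardizer and feature matrix have different columns")
  out <- fm
  out$values <- sweep(sweep(fm$values, 2, std$mean), 2, std$sd, "/")
  out
}

#' Export / import a feature matrix as CSV
#'
#' One row per trial: \code{trial}, the \code{CHANNEL_Band} feature
#' columns, and the \code{delay_s} target.
#'
#' @param fm A \code{feature_matrix}.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(trial = fm$trial_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$values, check.names = FALSE))
  df$delay_s <- fm$y
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  if (!all(c("trial", "delay_s") %in% names(df)))
    stop("feature CSV needs 'trial' and 'delay_s' columns")
  labels <- setdiff(names(df), c("trial", "delay_s"))
  structure(list(values = as.matrix(df[, labels, drop = FALSE]),
                 column_labels = labels, y = df$delay_s,
                 trial_ids = df$trial),
            class = "feature_matrix")
}
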