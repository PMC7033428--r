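# Repeated random-split evaluation: 11 random 75/25 train/test splits,
# per-split standardization and grid-search tuning, absolute test errors,
# and the per-subject aggregate MAE defined as the unweighted mean of the
# 11 per-split mean absolute errors.

#' Repeated random-split evaluation scheme
#'
#' @param n_repetitions Number of random train/test splits (default 11).
#' @param train_fraction Fraction of trials used for training and tuning
#'   (default 0.75); the training-set size is
#'   \code{round-half-away-from-zero(train_fraction * n)}.
#' @param inner_cv_folds Folds of the inner tuning CV (default 3).
#' @param base_seed Base seed; repetition r uses \code{base_seed + r}.
#'
#' @return An object of class \code{split_scheme}.
#' @export
split_scheme <- function(n_repetitions = 11L, train_fraction = 0.75,
                         inner_cv_folds = 3L, base_seed = 1L) {
  stopifnot(n_repetitions >= 1, train_fraction > 0, train_fraction < 1,
            inner_cv_folds >= 2)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 train_fraction = train_fraction,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 base_seed = as.integer(base_seed)),
            class = "split_scheme")
}

round_half_up <- function(x) floor(x + 0.5)

#' Generate the repeated train/test splits
#'
#' Each repetition is a random disjoint partition covering all trials.
#'
#' @param n_trials Number of trials (>= 8).
#' @param scheme A \code{\link{split_scheme}}.
#'
#' @return List of \code{n_repetitions} elements, each
#'   \code{list(train, test, seed)} with sorted 1-based indices.
#' @export
make_splits <- function(n_trials, scheme) {
  stopifnot(inherits(scheme, "split_scheme"))
  if (n_trials < 8L) stop("need at least 8 trials to evaluate")
  n_train <- as.integer(round_half_up(scheme$train_fraction * n_trials))
  if (n_train < 2L * scheme$inner_cv_folds)
    stop("training set of ", n_train, " trials is too small for ",
         scheme$inner_cv_folds, "-fold inner CV")
  if (n_train >= n_trials) stop("empty test set")
  lapply(seq_len(scheme$n_repetitions), function(r) {
    seed <- scheme$base_seed + r
    perm <- with_seed(seed, sample.int(n_trials))
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[(n_train + 1L):n_trials]),
         seed = seed)
  })
}

#' Repeated-split MAE aggregation
#'
#' The per-subject score is the unweighted mean of the per-repetition mean
#' absolute errors — not the pooled mean over all errors (the two differ
#' whenever repetitions have unequal test sizes).
#'
#' @param ae_list List of numeric vectors, one vector of absolute errors
#'   per repetition.
#' @return The aggregate MAE in seconds.
#' @export
#' @examples
#' mae_repeated(list(c(0.1, 0.1), c(0.2, 0.2))) # 0.15
mae_repeated <- function(ae_list) mean(vapply(ae_list, mean, numeric(1)))

aggregate_result <- function(ae_list) {
  all_ae <- unlist(ae_list)
  list(mae_s = mae_repeated(ae_list),
       sd_ae_s = stats::sd(all_ae),
       max_ae_s = max(all_ae))
}

#' Evaluate regression models on one subject's feature matrix
#'
#' For every repetition: split the trials, fit the standardizer on the
#' training rows only, tune each model by inner-CV grid search, refit on
#' the full training set, predict the held-out trials and record absolute
#' errors. The \code{shuffled_svr_rbf} algorithm additionally permutes the
#' training targets (per repetition, seeded) before tuning and fitting —
#' test targets stay true, so its score reflects predicting without EEG
#' information.
#'
#' @param fm A \code{\link{build_feature_matrix}} result (unstandardized).
#' @param specs List of \code{\link{model_spec}}s (a single spec is
#'   accepted).
#' @param scheme A \code{\link{split_scheme}}.
#'
#' @return An \code{eval_result}: per-algorithm repetition records
#'   (absolute errors, chosen hyperparameters, selected feature labels,
#'   seed) and an aggregate table with \code{mae_s} (mean over repetitions
#'   of per-repetition mean AE), \code{sd_ae_s} and \code{max_ae_s} over
#'   all pooled AEs.
#' @export
evaluate_subject <- function(fm, specs, scheme = split_scheme()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (!length(specs)) stop("no model specs given")
  names(specs) <- vapply(specs, function(s) s$algorithm, character(1))
  if (anyDuplicated(names(specs)))
    stop("duplicate algorithms in specs")
  n <- nrow(fm$values)
  splits <- make_splits(n, scheme)

  per_algo <- lapply(specs, function(spec) {
    reps <- vector("list", length(splits))
    for (r in seq_along(splits)) {
      sp <- splits[[r]]
      res <- tryCatch({
        std <- fit_standardizer(fm, sp$train)
        Z <- apply_standardizer(std, fm)$values
        y_train <- fm$y[sp$train]
        if (spec$algorithm == "shuffled_svr_rbf")
          y_train <- with_seed(scheme$base_seed + 10000L + r,
                               sample(y_train))
        tuned <- tune_and_fit(spec, Z[sp$train, , drop = FALSE], y_train,
                              n_folds = scheme$inner_cv_folds,
                              seed = sp$seed)
        pred <- predict(tuned$model, Z[sp$test, , drop = FALSE])
        list(ae = abs(pred - fm$y[sp$test]),
             params = tuned$params[setdiff(names(tuned$params), "k")],
             k = tuned$params$k,
             selected = fm$column_labels[tuned$selected],
             test_trials = fm$trial_ids[sp$test],
             seed = sp$seed)
      }, error = function(e) stop("repetition ", r, " (", spec$algorithm,
                                  "): ", conditionMessage(e), call. = FALSE))
      reps[[r]] <- res
    }
    c(list(repetitions = reps),
      aggregate_result(lapply(reps, `[[`, "ae")))
  })

  agg <- data.frame(
    algorithm = names(per_algo),
    mae_s = vapply(per_algo, `[[`, numeric(1), "mae_s"),
    sd_ae_s = vapply(per_algo, `[[`, numeric(1), "sd_ae_s"),
    max_ae_s = vapply(per_algo, `[[`, numeric(1), "max_ae_s"),
    row.names = NULL)
  structure(list(algorithms = per_algo, aggregates = agg, scheme = scheme),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: %d algorithm(s), %d repetitions>\n",
              length(x$algorithms), x$scheme$n_repetitions))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' Shuffled-label SVR baseline
#'
#' Convenience wrapper: runs \code{\link{evaluate_subject}} with the
#' \code{shuffled_svr_rbf} spec (same protocol as \code{svr_rbf}, but each
#' repetition's training targets are randomly permuted before tuning).
#' Comparable to learning to predict the average reaction time.
#'
#' @param fm A \code{feature_matrix}.
#' @param scheme A \code{\link{split_scheme}}.
#' @param spec Optional \code{model_spec} with algorithm
#'   \code{shuffled_svr_rbf} (default grids otherwise).
#'
#' @return An \code{eval_result}.
#' @export
shuffled_baseline <- function(fm, scheme = split_scheme(), spec = NULL) {
  if (is.null(spec)) spec <- model_spec("shuffled_svr_rbf")
  if (spec$algorithm != "shuffled_svr_rbf")
    stop("spec must use algorithm 'shuffled_svr_rbf'")
  evaluate_subject(fm, list(spec), scheme)
}

#' Selection frequency of SVR features
#'
#' Counts how often each (channel, band) feature entered the tuned SVR
#' feature subset across repetitions, per subject and pooled. Returns an
#' empty table (not an error) when no SVR variant was evaluated.
#'
#' @param results A single \code{eval_result} or a (optionally named) list
#'   of them, one per subject.
#' @param algorithm Which algorithm's selections to count (default
#'   \code{"svr_rbf"}).
#'
#' @return List with \code{per_subject} (data.frame subject/feature/count)
#'   and \code{pooled} (feature/count, sorted by decreasing count then
#'   label).
#' @export
summarize_selected_features <- function(results, algorithm = "svr_rbf") {
  if (inherits(results, "eval_result")) results <- list(results)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- paste0("subject", seq_along(results))
  rows <- list()
  for (s in names(results)) {
    algo <- results[[s]]$algorithms[[algorithm]]
    if (is.null(algo)) next
    feats <- unlist(lapply(algo$repetitions, `[[`, "selected"))
    if (!length(feats)) next
    tab <- table(feats)
    rows[[s]] <- data.frame(subject = s, feature = names(tab),
                            count = as.integer(tab), row.names = NULL)
  }
  if (!length(rows)) {
    empty <- data.frame(subject = character(0), feature = character(0),
                        count = integer(0))
    return(list(per_subject = empty,
                pooled = empty[, c("feature", "count")]))
  }
  per_subject <- do.call(rbind, rows)
  pooled <- stats::aggregate(count ~ feature, per_subject, sum)
  pooled <- pooled[order(-pooled$count, pooled$feature), , drop = FALSE]
  rownames(pooled) <- NULL
  per_subject <- per_subject[order(per_subject$subject,
                                   -per_subject$count,
                                   per_subject$feature), , drop = FALSE]
  rownames(per_subject) <- NULL
  list(per_subject = per_subject, pooled = pooled)
}
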