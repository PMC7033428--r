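# Regression algorithms and grid-search tuning. The estimators themselves
# come from established solvers (glmnet for the L1 models, e1071 for
# epsilon-SVR; kernel ridge is the closed-form dual solve); what this
# module owns is the tuning protocol: exhaustive grid search scored by
# 3-fold cross-validated MAE on the training rows, ties broken by grid
# order, and correlation-based feature ranking for the SVR variants.

#' Specify a regression model and its tuning grid
#'
#' @param algorithm One of \code{"lasso"}, \code{"lasso_lars"},
#'   \code{"kernel_ridge_rbf"}, \code{"svr_rbf"},
#'   \code{"shuffled_svr_rbf"} (identical to \code{svr_rbf} but trained on
#'   permuted training targets — the predict-the-average control).
#' @param grid Named list of hyperparameter candidate vectors; defaults
#'   per algorithm: lasso / lasso-LARS \code{lambda} = 7 log-spaced values
#'   in 1e-4..10; kernel ridge \code{alpha} in 1e-3..100 and \code{gamma}
#'   in 1e-4..10 (6 each); SVR \code{C} in 1e-2..1e3, \code{gamma} in
#'   1e-4..10, \code{epsilon} in \{0.01, 0.05, 0.1\} s.
#' @param k_grid Candidate counts of top-ranked features (SVR variants
#'   only; default \code{c(5, 10, 20, 40, 140)}, capped at the number of
#'   available features).
#'
#' @return An object of class \code{model_spec}.
#' @export
model_spec <- function(algorithm = c("lasso", "lasso_lars",
                                     "kernel_ridge_rbf", "svr_rbf",
                                     "shuffled_svr_rbf"),
                       grid = NULL, k_grid = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) {
    grid <- switch(algorithm,
      lasso = ,
      lasso_lars = list(lambda = 10^seq(-4, 1, length.out = 7)),
      kernel_ridge_rbf = list(alpha = 10^seq(-3, 2, length.out = 6),
                              gamma = 10^seq(-4, 1, length.out = 6)),
      svr_rbf = ,
      shuffled_svr_rbf = list(C = 10^seq(-2, 3, length.out = 6),
                              gamma = 10^seq(-4, 1, length.out = 6),
                              epsilon = c(0.01, 0.05, 0.1)))
  }
  if (!length(grid) || any(!lengths(grid)))
    stop("hyperparameter grid must be a non-empty list of non-empty vectors")
  is_svr <- algorithm %in% c("svr_rbf", "shuffled_svr_rbf")
  if (is_svr && is.null(k_grid)) k_grid <- c(5, 10, 20, 40, 140)
  if (!is_svr) k_grid <- NULL
  structure(list(algorithm = algorithm, grid = grid, k_grid = k_grid),
            class = "model_spec")
}

# Fit one algorithm at fixed hyperparameters on already-standardized X.
fit_one <- function(algorithm, X, y, params, sel = seq_len(ncol(X))) {
  Xs <- X[, sel, drop = FALSE]
  fit <- switch(algorithm,
    lasso = ,
    lasso_lars = glmnet::glmnet(Xs, y, alpha = 1, lambda = params$lambda,
                                standardize = FALSE, intercept = TRUE),
    kernel_ridge_rbf = krr_fit(Xs, y, params$alpha, params$gamma),
    svr_rbf = ,
    shuffled_svr_rbf = tryCatch(
      e1071::svm(x = Xs, y = y, type = "eps-regression",
                 kernel = "radial", cost = params$C, gamma = params$gamma,
                 epsilon = params$epsilon, scale = FALSE),
      error = function(e) {
        # epsilon tube wide enough to hold every target: no support
        # vectors; the SVR degenerates to predicting the training mean
        if (grepl("empty", conditionMessage(e), ignore.case = TRUE))
          structure(list(mean = mean(y)), class = "eegrt_constant")
        else stop(e)
      }))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 sel = sel), class = "eegrt_model")
}

#' @export
predict.eegrt_model <- function(object, newdata, ...) {
  Xs <- newdata[, object$sel, drop = FALSE]
  switch(object$algorithm,
    lasso = ,
    lasso_lars = as.numeric(stats::predict(object$fit, newx = Xs,
                                           s = object$params$lambda)),
    kernel_ridge_rbf = krr_predict(object$fit, Xs),
    svr_rbf = ,
    shuffled_svr_rbf = if (inherits(object$fit, "eegrt_constant"))
      rep(object$fit$mean, nrow(Xs))
    else as.numeric(stats::predict(object$fit, Xs)))
}

# Kernel ridge regression with an RBF kernel, closed-form dual solution:
# alpha_dual = (K + alpha I)^{-1} (y - mean(y)); the target mean serves as
# the intercept.
krr_fit <- function(X, y, alpha, gamma) {
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  y0 <- mean(y)
  dual <- solve(K + diag(alpha, n), y - y0)
  list(X = X, dual = dual, gamma = gamma, intercept = y0)
}

krr_predict <- function(fit, Xnew) {
  as.numeric(rbf_kernel(Xnew, fit$X, fit$gamma) %*% fit$dual + fit$intercept)
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Rank features by |Pearson correlation| with the training targets
# (decreasing; ties keep column order).
rank_features <- function(X, y) {
  r <- abs(suppressWarnings(stats::cor(X, y)))
  r[!is.finite(r)] <- 0
  order(r, decreasing = TRUE)
}

# Deterministic inner-CV fold assignment for n rows.
make_folds <- function(n, n_folds, seed) {
  if (n < 2L * n_folds)
    stop("too few training rows (", n, ") for ", n_folds, "-fold inner CV")
  with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Grid-search tuning and final fit
#'
#' Scores every point of the hyperparameter grid (for SVR variants the
#' grid is crossed with the candidate feature counts \code{k}) by mean MAE
#' over k-fold cross-validation on the training rows, picks the lowest
#' mean MAE (ties: first point in grid order), and refits on all training
#' rows with the winning settings. Feature ranking for the SVR variants is
#' computed once from the training rows by absolute Pearson correlation
#' with the targets.
#'
#' Expects features already standardized with training-row statistics
#' (see \code{\link{fit_standardizer}}).
#'
#' @param spec A \code{\link{model_spec}}.
#' @param X Standardized feature matrix (training rows only).
#' @param y Training targets in seconds.
#' @param n_folds Inner CV folds (default 3).
#' @param seed Seed for the fold assignment.
#'
#' @return List: \code{model} (supports \code{predict}),
#'   \code{params}, \code{selected} (feature column indices),
#'   \code{cv_mae} of the winning point, and the full \code{cv_table}.
#' @export
tune_and_fit <- function(spec, X, y, n_folds = 3L, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(X)
  folds <- make_folds(n, n_folds, seed)
  is_svr <- !is.null(spec$k_grid)

  grid_axes <- spec$grid
  if (is_svr) grid_axes$k <- pmin(spec$k_grid, ncol(X))
  tab <- expand.grid(grid_axes, KEEP.OUT.ATTRS = FALSE)
  tab <- tab[!duplicated(tab), , drop = FALSE]

  ranking <- if (is_svr) rank_features(X, y) else NULL

  scores <- numeric(nrow(tab))
  for (g in seq_len(nrow(tab))) {
    params <- as.list(tab[g, , drop = FALSE])
    sel <- if (is_svr) ranking[seq_len(params$k)] else seq_len(ncol(X))
    fold_mae <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      if (sum(!hold) < 2L) stop("inner fold with fewer than 2 training samples")
      m <- fit_one(spec$algorithm, X[!hold, , drop = FALSE], y[!hold],
                   params, sel)
      fold_mae[f] <- mean(abs(predict(m, X[hold, , drop = FALSE]) - y[hold]))
    }
    scores[g] <- mean(fold_mae)
  }
  best <- which.min(scores) # which.min returns the first minimum: grid-order ties
  params <- as.list(tab[best, , drop = FALSE])
  sel <- if (is_svr) ranking[seq_len(params$k)] else seq_len(ncol(X))
  model <- fit_one(spec$algorithm, X, y, params, sel)
  list(model = model, params = params, selected = sel,
       cv_mae = scores[best],
       cv_table = cbind(tab, cv_mae = scores))
}
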