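# Statistical layer: per-subject delay summaries, the Huber robust linear
# trend of delay versus time-in-session, one-way ANOVA across algorithms'
# absolute errors, and pairwise t-tests.

#' Robust linear trend via Huber IRLS
#'
#' Fits \code{y = intercept + slope * x} by iteratively reweighted least
#' squares with Huber's T criterion: residual scale is estimated as
#' MAD/0.6745, observations with \code{|r|/scale <= c} get weight 1 and
#' larger residuals weight \code{c / (|r|/scale)}. Iterates from the OLS
#' solution until the largest coefficient change is below \code{tol}. The
#' slope p-value uses the asymptotic normal statistic slope/se from the
#' final weighted fit.
#'
#' @param x Explanatory variable (event timestamps, s); not constant.
#' @param y Response (delays, s); \code{length(y) >= 3}.
#' @param tuning_c Huber threshold (default 1.345, the canonical 95%%
#'   Gaussian-efficiency choice). \code{Inf} reproduces OLS.
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 50); non-convergence
#'   is an error carrying the iteration trace.
#'
#' @return A \code{trend_fit}: slope, intercept, slope_se, slope_p, final
#'   weights (all in (0, 1]), n_iterations, converged flag.
#' @export
huber_rlm <- function(x, y, tuning_c = 1.345, tol = 1e-8, max_iter = 50L) {
  n <- length(y)
  if (length(x) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is constant; trend is undefined")
  X <- cbind(intercept = 1, slope = x)
  beta <- qr.solve(X, y)
  w <- rep(1, n)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- as.numeric(y - X %*% beta)
    scale <- stats::mad(r) # median(|r - median(r)|) / 0.6745
    if (scale <= .Machine$double.eps^0.5 * max(1, stats::sd(y))) {
      # (near-)exact fit: weights stay at 1, current beta is the solution
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    u <- abs(r) / scale
    w <- ifelse(u <= tuning_c, 1, tuning_c / u)
    fit <- stats::lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    trace <- c(trace, delta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("Huber IRLS did not converge in ", max_iter,
         " iterations; coefficient-change trace: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  r <- as.numeric(y - X %*% beta)
  sigma2 <- sum(w * r^2) / (n - 2)
  XtWX <- crossprod(X * sqrt(w))
  covb <- sigma2 * solve(XtWX)
  se <- sqrt(covb["slope", "slope"])
  z <- if (se > 0) beta[["slope"]] / se else NA_real_
  structure(list(slope = beta[["slope"]], intercept = beta[["intercept"]],
                 slope_se = se,
                 slope_p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
                 weights = w, n_iterations = iter, converged = converged),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: slope %.3g s/s (se %.3g, p %.3g), %d iterations>\n",
              x$slope, x$slope_se, x$slope_p, x$n_iterations))
  invisible(x)
}

#' Per-subject delay summary
#'
#' Min / median / max / sd (sample, 1/(n-1)) of the response delays plus
#' the Huber-robust linear trend of delay against cue timestamp — the
#' per-subject row of a session summary table.
#'
#' @param events An \code{\link{event_table}}.
#' @param ... Passed to \code{\link{huber_rlm}}.
#'
#' @return One-row data.frame: \code{min_s, median_s, max_s, sd_s,
#'   slope_s_per_s, slope_p, n_epochs}.
#' @export
summarize_delays <- function(events, ...) {
  stopifnot(inherits(events, "event_table"))
  d <- events$delay_s
  if (stats::sd(events$cue_onset_s) == 0 || length(d) < 3L || stats::sd(d) == 0) {
    slope <- 0; slope_p <- NA_real_
    if (length(d) >= 3L && stats::sd(events$cue_onset_s) > 0 && stats::sd(d) == 0) {
      # constant delays: exact flat fit
      slope <- 0; slope_p <- NA_real_
    }
  } else {
    fit <- huber_rlm(events$cue_onset_s, d, ...)
    slope <- fit$slope; slope_p <- fit$slope_p
  }
  data.frame(min_s = min(d), median_s = stats::median(d), max_s = max(d),
             sd_s = stats::sd(d), slope_s_per_s = slope, slope_p = slope_p,
             n_epochs = length(d))
}

#' One-way ANOVA across algorithms
#'
#' Classical equal-variance one-way ANOVA with the absolute prediction
#' errors as observations and the algorithms as groups.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#'
#' @return List: \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs >= 2 observations")
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))))
    stop("zero within-group variance in every group; F is undefined")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  ft <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}

#' Pairwise t-tests between groups
#'
#' Two-sided t-tests for every unordered pair of groups. The default is
#' the unpaired Welch test (group sizes may differ when trials were
#' dropped); paired mode requires equal lengths with matched ordering. A
#' pair whose paired differences are all zero is reported as p = 1 by
#' convention. Raw p-values are returned by default; set \code{p_adjust}
#' for a multiplicity correction.
#'
#' @param groups Named list of numeric vectors.
#' @param paired Use paired tests (default FALSE).
#' @param p_adjust Method for \code{\link[stats]{p.adjust}} applied to the
#'   upper triangle (default \code{"none"}).
#'
#' @return Symmetric matrix of p-values with \code{NA} on the diagonal.
#' @export
pairwise_ttests <- function(groups, paired = FALSE, p_adjust = "none") {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  P <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  idx <- utils::combn(k, 2)
  pvals <- apply(idx, 2, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    if (paired) {
      if (length(a) != length(b))
        stop("paired mode requires equal group lengths (",
             names(groups)[ij[1]], " vs ", names(groups)[ij[2]], ")")
      d <- a - b
      if (all(d == 0)) return(1) # degenerate: identical paired samples
      return(stats::t.test(a, b, paired = TRUE)$p.value)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  })
  pvals <- stats::p.adjust(pvals, method = p_adjust)
  for (j in seq_len(ncol(idx))) {
    P[idx[1, j], idx[2, j]] <- pvals[j]
    P[idx[2, j], idx[1, j]] <- pvals[j]
  }
  P
}
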