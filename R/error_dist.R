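#' Symmetrize a pairwise error sample
#'
#' Pairwise ddG errors over unordered pairs have an arbitrary overall sign
#' (swapping the two compounds of a pair negates the error). Symmetrization
#' concatenates the N(N-1)/2 unordered-pair errors with their negation,
#' yielding all N(N-1) ordered pairs: the sample mean becomes exactly zero
#' and every odd moment vanishes, while RMSE, MUE and all even moments are
#' unchanged.
#'
#' @param errors Non-empty numeric vector of signed unordered-pair errors,
#'   possibly pooled over several series.
#' @return Numeric vector of length `2 * length(errors)`.
#' @export
symmetrize_errors <- function(errors) {
  if (length(errors) < 1L) stop("empty error sample", call. = FALSE)
  c(errors, -errors)
}

#' Maximum-likelihood Student-t fit to symmetrized errors
#'
#' Fits a scaled Student-t distribution to a symmetrized error sample by
#' maximum likelihood, with the location fixed at 0 (symmetrization makes a
#' free location redundant and numerically fragile) and the scale free. A
#' small degrees-of-freedom estimate means fatter-than-Gaussian tails; the
#' estimate is capped at 1000 and flagged effectively Gaussian above 100.
#'
#' The likelihood is maximized over (log scale, log df) with L-BFGS-B,
#' initialized from the sample's excess kurtosis.
#'
#' @param sym_errors Symmetrized error sample, length >= 10.
#' @param df_max Upper cap for the degrees-of-freedom estimate.
#' @return A list with `df`, `scale`, `loglik`, `effectively_gaussian`
#'   (df > 100) and `convergence` (0 means converged).
#' @export
fit_t_errors <- function(sym_errors, df_max = 1000) {
  n <- length(sym_errors)
  if (n < 10L) stop("need at least 10 samples for a t fit", call. = FALSE)
  s2 <- mean(sym_errors^2) # mean is 0 by symmetrization
  if (s2 <= 0) stop("degenerate sample: zero variance", call. = FALSE)

  # moment-based start: excess kurtosis k of a t is 6/(df - 4)
  k <- mean(sym_errors^4) / s2^2 - 3
  df0 <- if (is.finite(k) && k > 0.05) min(4 + 6 / k, 50) else 30
  scale0 <- sqrt(s2 * if (df0 > 2.5) (df0 - 2) / df0 else 0.5)

  nll <- function(par) {
    s <- exp(par[1])
    v <- exp(par[2])
    -sum(stats::dt(sym_errors / s, df = v, log = TRUE) - log(s))
  }
  fit <- stats::optim(
    par = c(log(scale0), log(df0)), fn = nll, method = "L-BFGS-B",
    lower = c(log(s2) / 2 - 15, log(0.1)),
    upper = c(log(s2) / 2 + 15, log(df_max)),
    control = list(maxit = 500)
  )
  if (fit$convergence != 0 && fit$convergence != 52) {
    stop(
      "t-distribution MLE failed to converge (code ", fit$convergence,
      "): ", fit$message,
      call. = FALSE
    )
  }
  df_hat <- exp(fit$par[2])
  list(
    df = df_hat,
    scale = exp(fit$par[1]),
    loglik = -fit$value,
    effectively_gaussian = df_hat > 100,
    convergence = fit$convergence
  )
}

#' Empirical tail fractions of an error sample
#'
#' `fraction_within()` is the proportion of errors with absolute value at or
#' below `threshold`; `fraction_beyond()` the proportion strictly above.
#'
#' @param errors Numeric error sample.
#' @param threshold Positive threshold in kcal mol^-1.
#' @return A fraction in \[0, 1\].
#' @export
fraction_within <- function(errors, threshold) {
  check_threshold(threshold)
  mean(abs(errors) <= threshold)
}

#' @rdname fraction_within
#' @export
fraction_beyond <- function(errors, threshold) {
  check_threshold(threshold)
  mean(abs(errors) > threshold)
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  invisible(TRUE)
}

#' Model-expected fractions within a threshold
#'
#' Expected proportion of absolute errors at or below a threshold under a
#' zero-mean Gaussian with standard deviation `sd`, or a zero-location
#' Student-t with `df` degrees of freedom and scale `scale`. Used to compare
#' observed tail fractions against what a Gaussian with sd equal to the
#' pairwise RMSE would predict.
#'
#' @param sd,scale Positive dispersion parameters (kcal mol^-1).
#' @param df Positive degrees of freedom.
#' @param threshold Positive threshold (kcal mol^-1).
#' @return Expected fraction in \[0, 1\].
#' @examples
#' gaussian_expected_within(1, 1) # 0.6827
#' gaussian_expected_within(1.25, 1) # what sd = RMSE would predict at 1 kcal/mol
#' @export
gaussian_expected_within <- function(sd, threshold) {
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  check_threshold(threshold)
  2 * stats::pnorm(threshold / sd) - 1
}

#' @rdname gaussian_expected_within
#' @export
t_expected_within <- function(df, scale, threshold) {
  if (!is.numeric(df) || df <= 0) stop("`df` must be positive", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0) stop("`scale` must be positive", call. = FALSE)
  check_threshold(threshold)
  2 * stats::pt(threshold / scale, df = df) - 1
}

#' Characterize a pooled pairwise error distribution
#'
#' Builds the symmetrized sample from pooled unordered-pair errors (each
#' pair counts once, no reweighting across series), then summarizes it:
#' Gaussian sd (the RMS, since the symmetrized mean is 0), maximum
#' likelihood Student-t parameters, observed fractions within 1 and beyond
#' 2 kcal mol^-1, and the model-expected counterparts.
#'
#' @param pair_errors Pooled unordered-pair error vector (kcal mol^-1),
#'   length >= 5.
#' @param thresholds Two positive thresholds, the "within" and the "beyond"
#'   one (default 1 and 2 kcal mol^-1).
#' @return An object of class `error_dist_fit`: a list with `n_pairs`
#'   (symmetrized count), `gaussian_sd`, `t_df`, `t_scale`, `frac_within_1`,
#'   `frac_beyond_2`, `expected` (tibble of model-expected fractions) and
#'   the symmetrized sample in `sym_errors`.
#' @export
error_dist_fit <- function(pair_errors, thresholds = c(1, 2)) {
  stopifnot(length(thresholds) == 2L, all(thresholds > 0))
  sym <- symmetrize_errors(pair_errors)
  gaussian_sd <- sqrt(mean(sym^2))
  tfit <- fit_t_errors(sym)
  expected <- tibble::tibble(
    threshold = thresholds,
    gaussian_within = vapply(
      thresholds, function(t) gaussian_expected_within(gaussian_sd, t), 0
    ),
    t_within = vapply(
      thresholds, function(t) t_expected_within(tfit$df, tfit$scale, t), 0
    )
  )
  structure(
    list(
      n_pairs = length(sym),
      gaussian_sd = gaussian_sd,
      t_df = tfit$df,
      t_scale = tfit$scale,
      t_loglik = tfit$loglik,
      effectively_gaussian = tfit$effectively_gaussian,
      frac_within_1 = fraction_within(sym, thresholds[1]),
      frac_beyond_2 = fraction_beyond(sym, thresholds[2]),
      thresholds = thresholds,
      expected = expected,
      sym_errors = sym
    ),
    class = "error_dist_fit"
  )
}

#' @export
print.error_dist_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<error_dist_fit> %d symmetrized pair errors\n",
      "  Gaussian sd: %.2f kcal/mol; t fit: df = %.1f, scale = %.2f%s\n",
      "  within %g kcal/mol: %.1f%% (Gaussian would give %.1f%%)\n",
      "  beyond %g kcal/mol: %.1f%%\n"
    ),
    x$n_pairs, x$gaussian_sd, x$t_df, x$t_scale,
    if (x$effectively_gaussian) " (effectively Gaussian)" else "",
    x$thresholds[1], 100 * x$frac_within_1, 100 * x$expected$gaussian_within[1],
    x$thresholds[2], 100 * x$frac_beyond_2
  ))
  invisible(x)
}

#' Histogram of a symmetrized error sample
#'
#' Fixed-width bins (default 0.25 kcal mol^-1) centered on zero, for
#' exporting the error distribution alongside the fitted densities.
#'
#' @param sym_errors Symmetrized error sample.
#' @param binwidth Positive bin width in kcal mol^-1.
#' @return Tibble with `mid`, `count`, `density`.
#' @export
error_histogram <- function(sym_errors, binwidth = 0.25) {
  stopifnot(binwidth > 0, length(sym_errors) > 0)
  half <- binwidth / 2
  lim <- max(abs(sym_errors))
  breaks <- seq(-half - binwidth * ceiling((lim - half) / binwidth + 1), by = binwidth,
    length.out = 2 * (ceiling((lim - half) / binwidth) + 2) + 1
  )
  h <- graphics::hist(sym_errors, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0 | (abs(h$mids) <= lim + binwidth)
  tibble::tibble(mid = h$mids[keep], count = h$counts[keep], density = h$density[keep])
}
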