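#' Percentile bootstrap confidence interval for a weighted aggregate
#'
#' Resamples whole comparisons (assay comparisons or FEP graphs) with
#' replacement -- each item's weight travels with it -- recomputes the
#' weighted statistic for every replicate, and reports the percentile
#' interval. The resampling unit is always the comparison, never the
#' individual compound, so the interval reflects between-comparison
#' variability.
#'
#' @param values Per-comparison metric values (e.g. RMSEs), length M >= 1.
#' @param weights Positive per-comparison weights (compound or edge counts).
#' @param statistic `"weighted_rmse"` for the quadratic-mean aggregation of
#'   RMSEs, `"weighted_mean"` for the linear aggregation used for MUE,
#'   R-squared and Kendall tau.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; required so intervals are reproducible.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble of class `aggregate_result`: `point`, `ci_low`,
#'   `ci_high`, `M` (number of comparisons), `n_boot`, `statistic`.
#' @examples
#' bootstrap_ci(c(0.8, 1.1, 0.9), c(10, 25, 14), seed = 1)
#' @export
bootstrap_ci <- function(values, weights = rep(1, length(values)),
                         statistic = c("weighted_rmse", "weighted_mean"),
                         n_boot = 10000L, seed, conf = 0.95) {
  statistic <- match.arg(statistic)
  check_weights(values, weights)
  if (missing(seed)) stop("`seed` is required for a reproducible bootstrap", call. = FALSE)
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  m <- length(values)
  agg <- function(v, w) {
    if (statistic == "weighted_rmse") sqrt(sum(w * v^2) / sum(w)) else sum(w * v) / sum(w)
  }
  point <- agg(values, weights)
  reps <- withr::with_seed(seed, {
    idx <- matrix(sample.int(m, n_boot * m, replace = TRUE), nrow = n_boot)
    v <- matrix(values[idx], nrow = n_boot)
    w <- matrix(weights[idx], nrow = n_boot)
    if (statistic == "weighted_rmse") {
      sqrt(rowSums(w * v^2) / rowSums(w))
    } else {
      rowSums(w * v) / rowSums(w)
    }
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  out <- tibble::tibble(
    point = point, ci_low = ci[1], ci_high = ci[2],
    M = m, n_boot = as.integer(n_boot), statistic = statistic
  )
  class(out) <- c("aggregate_result", class(out))
  out
}
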