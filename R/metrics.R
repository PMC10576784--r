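#' All-pairs relative free energy errors
#'
#' For every unordered pair of compounds (i, j) the pairwise error is
#' `(pred_i - pred_j) - (exp_i - exp_j)`: the discrepancy between predicted
#' and experimental ddG. Pairwise errors are invariant to an additive offset
#' on either input, so they are unaffected by the unknown constant in
#' IC50-derived or graph-inferred dG values, and do not depend on the
#' topology of a perturbation graph.
#'
#' @param pred,exp Paired numeric dG vectors (kcal mol^-1), length N >= 2.
#' @return Numeric vector of N(N-1)/2 signed errors, pairs ordered i < j.
#' @examples
#' pairwise_errors(c(0, 1, 2), c(0, 1.5, 2))
#' @export
pairwise_errors <- function(pred, exp) {
  n <- length(pred)
  if (length(exp) != n) stop("`pred` and `exp` must be paired", call. = FALSE)
  if (n < 2L) stop("need at least 2 compounds for pairwise errors", call. = FALSE)
  d <- outer(pred, pred, "-") - outer(exp, exp, "-")
  dt <- t(d)
  dt[lower.tri(dt)] # all i < j pairs in lexicographic (i, j) order
}

#' Edgewise prediction errors on a perturbation graph
#'
#' The edgewise error of edge (a, b) is `ddg_pred - (exp_dG_a - exp_dG_b)`,
#' using the raw edge predictions (not the cycle-closure fitted values).
#' Unlike pairwise errors these depend on which perturbations were simulated.
#'
#' @param g A [perturbation_graph()].
#' @param exp_dg Named numeric vector of experimental dG keyed by compound
#'   id; defaults to the values stored on the graph.
#' @return Numeric vector of signed errors, one per edge.
#' @export
edgewise_errors <- function(g, exp_dg = NULL) {
  stopifnot(inherits(g, "perturbation_graph"))
  if (is.null(exp_dg)) {
    exp_dg <- stats::setNames(g$nodes$exp_dg, g$nodes$compound_id)
  }
  ea <- unname(exp_dg[g$edges$ligand_a])
  eb <- unname(exp_dg[g$edges$ligand_b])
  if (anyNA(ea) || anyNA(eb)) {
    missing <- unique(c(
      g$edges$ligand_a[is.na(ea)], g$edges$ligand_b[is.na(eb)]
    ))
    stop("experimental dG missing for: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  g$edges$ddg_pred - (ea - eb)
}

#' Root-mean-square and mean unsigned error
#'
#' @param errors Non-empty numeric vector of signed errors (kcal mol^-1).
#' @return A single value in kcal mol^-1. `rmse()` is always >= `mue()`.
#' @export
rmse <- function(errors) {
  if (length(errors) < 1L) stop("empty error vector", call. = FALSE)
  sqrt(mean(errors^2))
}

#' @rdname rmse
#' @export
mue <- function(errors) {
  if (length(errors) < 1L) stop("empty error vector", call. = FALSE)
  mean(abs(errors))
}

#' Weighted aggregation of RMSEs across series or graphs
#'
#' Aggregates M per-comparison RMSEs as
#' `sqrt( sum(w_i * RMSE_i^2) / sum(w_i) )`, i.e. a weighted quadratic mean.
#' The weighting rule is the number of compounds for pairwise RMSEs and the
#' number of edges for edgewise RMSEs, so that larger series contribute
#' proportionally.
#'
#' @param rmse_values Numeric vector of per-comparison RMSEs.
#' @param weights Positive weights, same length.
#' @return Aggregate RMSE (kcal mol^-1).
#' @examples
#' weighted_rmse(c(1, 2), c(3, 1)) # sqrt(7/4)
#' @export
weighted_rmse <- function(rmse_values, weights) {
  check_weights(rmse_values, weights)
  sqrt(sum(weights * rmse_values^2) / sum(weights))
}

#' Weighted linear mean of per-comparison metrics
#'
#' Used for aggregating MUE, R-squared and Kendall tau, where each
#' comparison is weighted by its number of compounds.
#'
#' @param values Numeric vector of per-comparison metric values.
#' @param weights Positive weights, same length.
#' @return `sum(w * v) / sum(w)`.
#' @export
weighted_mean_metric <- function(values, weights) {
  check_weights(values, weights)
  sum(weights * values) / sum(weights)
}

check_weights <- function(values, weights) {
  if (length(values) != length(weights) || length(values) < 1L) {
    stop("`values` and `weights` must be non-empty and the same length",
      call. = FALSE
    )
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Correlation metrics for rank-ordering ability
#'
#' `r_squared()` is the squared Pearson correlation, which is offset- and
#' scale-invariant: inter-assay offsets (irrelevant for rank ordering) do
#' not penalize it. `kendall_tau()` is the tie-corrected tau-b rank
#' correlation; affinity values rounded to assay precision routinely
#' produce ties.
#'
#' @param x,y Paired numeric vectors, length >= 2; each must have non-zero
#'   variance.
#' @return A value in \[0, 1\] for `r_squared()`, \[-1, 1\] for
#'   `kendall_tau()`.
#' @export
r_squared <- function(x, y) {
  check_correlation_input(x, y)
  stats::cor(x, y)^2
}

#' @rdname r_squared
#' @export
kendall_tau <- function(x, y) {
  check_correlation_input(x, y)
  stats::cor(x, y, method = "kendall")
}

check_correlation_input <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("paired vectors of length >= 2 required", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  invisible(TRUE)
}

#' Full metric suite for one prediction-vs-experiment comparison
#'
#' Computes pairwise RMSE/MUE, squared Pearson correlation and Kendall
#' tau-b from paired dG vectors; when a perturbation graph is supplied,
#' edgewise RMSE/MUE from its raw edge predictions are added. Pairwise
#' metrics should be computed from graph-consistent node dG values (see
#' [infer_node_dgs()]), edgewise metrics always from the raw edges.
#'
#' @param pred,exp Paired numeric dG vectors (kcal mol^-1).
#' @param label Identifier for the comparison.
#' @param graph Optional [perturbation_graph()] for edgewise errors.
#' @param exp_dg Optional named experimental dG vector for the graph's
#'   nodes (defaults to values stored on the graph).
#' @return A one-row tibble of class `comparison_metrics` with columns
#'   `label`, `n_compounds`, `n_edges`, `pairwise_rmse`, `pairwise_mue`,
#'   `edgewise_rmse`, `edgewise_mue`, `r_squared`, `kendall_tau`.
#'   Correlation columns are NA when fewer than 3 compounds are available.
#' @export
comparison_metrics <- function(pred, exp, label = "comparison",
                               graph = NULL, exp_dg = NULL) {
  pe <- pairwise_errors(pred, exp)
  n <- length(pred)
  r2 <- tau <- NA_real_
  if (n >= 3L) {
    r2 <- r_squared(pred, exp)
    tau <- kendall_tau(pred, exp)
  }
  e_rmse <- e_mue <- NA_real_
  n_edges <- NA_integer_
  if (!is.null(graph)) {
    ee <- edgewise_errors(graph, exp_dg)
    e_rmse <- rmse(ee)
    e_mue <- mue(ee)
    n_edges <- nrow(graph$edges)
  }
  out <- tibble::tibble(
    label = label,
    n_compounds = n,
    n_edges = n_edges,
    pairwise_rmse = rmse(pe),
    pairwise_mue = mue(pe),
    edgewise_rmse = e_rmse,
    edgewise_mue = e_mue,
    r_squared = r2,
    kendall_tau = tau
  )
  class(out) <- c("comparison_metrics", class(out))
  out
}
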