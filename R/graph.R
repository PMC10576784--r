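#' Construct a perturbation graph
#'
#' A perturbation graph has ligands as nodes and predicted relative binding
#' free energies (ddG) as directed edges. An edge (a, b) carries the
#' prediction for the a -> b perturbation, i.e. ddG_ab = dG_a - dG_b under
#' the package's sign convention. Edges may carry standard errors; duplicate
#' (a, b) edges are kept as independent repeat observations.
#'
#' @param edges A data frame with columns `ligand_a`, `ligand_b`, `ddg_pred`
#'   and optionally `ddg_se` (kcal mol^-1).
#' @param exp_dg Optional named numeric vector or data frame
#'   (`compound_id`, `exp_dg`) of experimental dG values for (a subset of)
#'   the nodes.
#' @return An object of class `perturbation_graph` with elements `edges`
#'   (tibble), `nodes` (tibble with `compound_id`, `exp_dg`).
#' @examples
#' g <- perturbation_graph(data.frame(
#'   ligand_a = c("a", "b"), ligand_b = c("b", "c"), ddg_pred = c(1, 1)
#' ))
#' infer_node_dgs(g)
#' @export
perturbation_graph <- function(edges, exp_dg = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("ligand_a", "ligand_b", "ddg_pred")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0L) {
    stop("edge table lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"ddg_se" %in% names(edges)) edges$ddg_se <- NA_real_
  edges$ligand_a <- as.character(edges$ligand_a)
  edges$ligand_b <- as.character(edges$ligand_b)
  if (nrow(edges) < 1L) stop("graph needs at least one edge", call. = FALSE)
  if (any(edges$ligand_a == edges$ligand_b)) {
    stop("self-edges are not allowed in a perturbation graph", call. = FALSE)
  }
  if (anyNA(edges$ddg_pred)) stop("ddg_pred must not contain NA", call. = FALSE)
  node_ids <- sort(unique(c(edges$ligand_a, edges$ligand_b)))
  if (length(node_ids) < 2L) stop("graph needs at least two nodes", call. = FALSE)

  nodes <- tibble::tibble(compound_id = node_ids, exp_dg = NA_real_)
  if (!is.null(exp_dg)) {
    if (is.data.frame(exp_dg)) {
      exp_dg <- stats::setNames(exp_dg$exp_dg, exp_dg$compound_id)
    }
    hit <- match(nodes$compound_id, names(exp_dg))
    nodes$exp_dg <- unname(exp_dg[hit])
  }
  structure(
    list(edges = edges[c("ligand_a", "ligand_b", "ddg_pred", "ddg_se")], nodes = nodes),
    class = "perturbation_graph"
  )
}

#' @export
print.perturbation_graph <- function(x, ...) {
  cat(sprintf(
    "<perturbation_graph> %d ligands, %d edges (%d with experimental dG)\n",
    nrow(x$nodes), nrow(x$edges), sum(!is.na(x$nodes$exp_dg))
  ))
  invisible(x)
}

graph_components <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[c("ligand_a", "ligand_b")],
    directed = FALSE, vertices = g$nodes$compound_id
  )
  comp <- igraph::components(ig)
  split(names(comp$membership), comp$membership)
}

assert_connected <- function(g) {
  comps <- graph_components(g)
  if (length(comps) > 1L) {
    stop(
      "perturbation graph is disconnected; components: ",
      paste(vapply(comps, function(x) paste(x, collapse = ","), ""),
        collapse = " | "
      ),
      call. = FALSE
    )
  }
  invisible(g)
}

#' Infer per-ligand dG values from a perturbation graph
#'
#' Solves the cycle-closure problem by weighted least squares: finds node
#' free energies dG minimizing `sum_e w_e (dG_a - dG_b - ddg_pred_e)^2` over
#' all edges. Because only differences are observable, dG is identifiable up
#' to an additive constant; the gauge is fixed by mean-centering (the
#' minimum-norm least-squares solution), so results are invariant to node
#' relabeling.
#'
#' Edge weights are `1/ddg_se^2` when every edge carries a positive standard
#' error; otherwise unit weights are used (a warning is issued if only some
#' edges have SEs, to avoid silently mixing scales).
#'
#' Node standard errors come from the pseudo-inverse of the weighted
#' normal matrix. With edge SEs they are on the reported SE scale; with unit
#' weights the residual variance is estimated from the cycle residuals
#' (zero when the graph is a tree or residuals vanish).
#'
#' @param g A [perturbation_graph()]; must be connected.
#' @return A tibble of class `node_estimates` with columns `compound_id`,
#'   `dg` (mean-centered, kcal mol^-1) and `dg_se`.
#' @export
infer_node_dgs <- function(g) {
  stopifnot(inherits(g, "perturbation_graph"))
  assert_connected(g)
  edges <- g$edges
  ids <- g$nodes$compound_id
  n <- length(ids)
  m <- nrow(edges)
  ia <- match(edges$ligand_a, ids)
  ib <- match(edges$ligand_b, ids)

  se <- edges$ddg_se
  have_se <- !is.na(se) & se > 0
  if (all(have_se)) {
    w <- 1 / se^2
    weighted <- TRUE
  } else {
    if (any(have_se)) {
      warning(
        "some but not all edges carry standard errors; falling back to unit weights",
        call. = FALSE
      )
    }
    w <- rep(1, m)
    weighted <- FALSE
  }

  # incidence matrix A: row e has +1 at a, -1 at b so A %*% dg approximates ddg
  A <- matrix(0, m, n)
  A[cbind(seq_len(m), ia)] <- 1
  A[cbind(seq_len(m), ib)] <- A[cbind(seq_len(m), ib)] - 1
  L <- crossprod(A, w * A) # weighted graph Laplacian
  rhs <- crossprod(A, w * edges$ddg_pred)
  Lp <- MASS::ginv(L)
  dg <- drop(Lp %*% rhs) # minimum-norm => sum(dg) = 0, i.e. mean-centered
  dg <- dg - mean(dg) # exact centering against roundoff

  if (weighted) {
    var_dg <- diag(Lp)
  } else {
    resid <- edges$ddg_pred - (dg[ia] - dg[ib])
    dof <- m - (n - 1L)
    sigma2 <- if (dof > 0L) sum(w * resid^2) / dof else 0
    var_dg <- sigma2 * diag(Lp)
  }
  out <- tibble::tibble(
    compound_id = ids,
    dg = dg,
    dg_se = sqrt(pmax(var_dg, 0))
  )
  class(out) <- c("node_estimates", class(out))
  out
}

#' Graph-consistent fitted edge ddG values
#'
#' Given inferred node free energies, the fitted ddG of every edge (a, b) is
#' `dG_a - dG_b`. By construction the signed sum of fitted ddG values around
#' any cycle is zero, which is the cycle-closure consistency condition.
#'
#' @param nodes A `node_estimates` tibble from [infer_node_dgs()] (or any
#'   data frame with `compound_id` and `dg`).
#' @param g The [perturbation_graph()] the estimates belong to.
#' @return The graph's edge tibble with added columns `ddg_fit` and
#'   `residual` (`ddg_pred - ddg_fit`).
#' @export
consistent_edge_ddgs <- function(nodes, g) {
  stopifnot(inherits(g, "perturbation_graph"))
  idx_a <- match(g$edges$ligand_a, nodes$compound_id)
  idx_b <- match(g$edges$ligand_b, nodes$compound_id)
  if (anyNA(idx_a) || anyNA(idx_b)) {
    missing <- unique(c(
      g$edges$ligand_a[is.na(idx_a)], g$edges$ligand_b[is.na(idx_b)]
    ))
    stop("node estimates missing for: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- g$edges
  out$ddg_fit <- nodes$dg[idx_a] - nodes$dg[idx_b]
  out$residual <- out$ddg_pred - out$ddg_fit
  out
}

#' Shift predicted dG values onto the experimental mean
#'
#' Predicted node free energies are defined only up to an additive constant.
#' For display against experiment the constant is fixed by matching means:
#' the predictions are shifted so their mean equals the experimental mean.
#' Correlation, rank statistics and all pairwise differences are unchanged.
#'
#' @param pred,exp Equal-length numeric vectors of predicted and
#'   experimental dG values, paired by compound.
#' @return `pred + (mean(exp) - mean(pred))`.
#' @export
align_offset <- function(pred, exp) {
  if (length(pred) != length(exp) || length(pred) < 1L) {
    stop("`pred` and `exp` must be paired vectors of equal length >= 1",
      call. = FALSE
    )
  }
  pred + (mean(exp) - mean(pred))
}
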