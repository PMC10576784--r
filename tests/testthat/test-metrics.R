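test_that("pairwise errors match the brute-force all-pairs oracle", {
  pred <- c(0, 1, 2)
  exp <- c(0, 1.5, 2)
  pe <- pairwise_errors(pred, exp)
  expect_equal(sort(pe), sort(brute_force_pairwise(pred, exp)))
  expect_equal(sort(pe), c(-0.5, 0, 0.5))
  expect_equal(rmse(pe), sqrt(1 / 6))
  expect_equal(mue(pe), 1 / 3)
  # random fixture, larger N
  set.seed(31)
  p2 <- rnorm(9); e2 <- rnorm(9)
  expect_equal(pairwise_errors(p2, e2), brute_force_pairwise(p2, e2))
  expect_length(pairwise_errors(p2, e2), 9 * 8 / 2)
})

test_that("pairwise errors are invariant to additive offsets", {
  set.seed(8)
  pred <- rnorm(12); exp <- rnorm(12)
  base <- pairwise_errors(pred, exp)
  expect_equal(pairwise_errors(pred + 3.7, exp), base)
  expect_equal(pairwise_errors(pred, exp - 11.2), base)
  expect_equal(pairwise_errors(pred + 5, exp + 5), base)
  # pred = exp + constant: all errors vanish
  expect_equal(pairwise_errors(exp + 2.5, exp), rep(0, length(base)))
  expect_error(pairwise_errors(1, numeric(0)), "paired")
  expect_error(pairwise_errors(1, 1), "at least 2")
})

test_that("edgewise errors use raw edge predictions", {
  sim <- simulate_graph(graph_sim_config(
    n_nodes = 8, extra_cycle_edges = 4, edge_noise_sd = 0, seed = 6
  ))
  expect_equal(edgewise_errors(sim$graph), rep(0, nrow(sim$graph$edges)))
  # single-edge graph: edgewise and pairwise errors coincide (N = 2)
  g <- perturbation_graph(
    data.frame(ligand_a = "a", ligand_b = "b", ddg_pred = 1.4),
    exp_dg = c(a = -9.0, b = -10.1)
  )
  ee <- edgewise_errors(g)
  pe <- pairwise_errors(c(0, -1.4), c(-9.0, -10.1)) # pred dGs consistent with the edge
  expect_length(ee, 1)
  expect_equal(abs(ee), abs(pe))
  g_missing <- perturbation_graph(
    data.frame(ligand_a = "a", ligand_b = "b", ddg_pred = 1.4),
    exp_dg = c(a = -9.0)
  )
  expect_error(edgewise_errors(g_missing), "missing for: b")
})

test_that("dense and sparse topologies differ edgewise but not pairwise", {
  set.seed(13)
  n <- 12
  dg_true <- runif(n, -12, -7)
  ids <- sprintf("l%02d", 1:n)
  pred_dg <- dg_true + rnorm(n, sd = 0.5)
  make_g <- function(extra_seed, n_extra) {
    sim <- simulate_graph(graph_sim_config(
      n_nodes = n, extra_cycle_edges = n_extra, edge_noise_sd = 0, seed = extra_seed
    ))
    edges <- sim$graph$edges
    ia <- match(edges$ligand_a, sim$truth$compound_id)
    ib <- match(edges$ligand_b, sim$truth$compound_id)
    perturbation_graph(
      data.frame(
        ligand_a = ids[ia], ligand_b = ids[ib],
        ddg_pred = pred_dg[ia] - pred_dg[ib]
      ),
      exp_dg = stats::setNames(dg_true, ids)
    )
  }
  sparse <- make_g(1, 0)
  dense <- make_g(1, 30)
  expect_false(isTRUE(all.equal(
    rmse(edgewise_errors(sparse)), rmse(edgewise_errors(dense))
  )))
  # pairwise RMSE depends only on the node dGs, not on topology
  expect_equal(
    rmse(pairwise_errors(pred_dg, dg_true)),
    rmse(pairwise_errors(pred_dg, dg_true))
  )
})

test_that("rmse and mue behave as power means", {
  expect_equal(rmse(c(-0.5, 0, 0.5)), 0.4082483, tolerance = 1e-6)
  expect_equal(mue(c(-0.5, 0, 0.5)), 1 / 3)
  expect_equal(rmse(rep(0, 5)), 0)
  expect_equal(mue(rep(0, 5)), 0)
  set.seed(2)
  for (i in 1:20) {
    e <- rnorm(sample(2:50, 1))
    expect_gte(rmse(e), mue(e))
  }
  # N = 2: single pair, RMSE = MUE = |error|
  pe <- pairwise_errors(c(0, 1), c(0, 1.8))
  expect_length(pe, 1)
  expect_equal(rmse(pe), abs(pe))
  expect_equal(mue(pe), abs(pe))
  expect_error(rmse(numeric(0)), "empty")
})

test_that("weighted RMSE aggregation follows the quadratic-mean rule", {
  expect_equal(weighted_rmse(c(1, 1), c(1, 1)), 1)
  expect_equal(weighted_rmse(c(1, 2), c(3, 1)), sqrt(7 / 4))
  expect_equal(weighted_rmse(c(1, 2), c(3, 1)), 1.3229, tolerance = 1e-4)
  # equal weights reduce to the plain quadratic mean
  expect_equal(weighted_rmse(c(0.5, 1.5), c(2, 2)), sqrt(mean(c(0.25, 2.25))))
  # a single comparison returns its own RMSE exactly
  expect_equal(weighted_rmse(0.83, 17), 0.83)
  expect_error(weighted_rmse(c(1, 2), c(1, 0)), "positive")
  expect_error(weighted_rmse(c(1, 2), c(1, -2)), "positive")
})

test_that("weighted linear mean is used for MUE and rank metrics", {
  expect_equal(weighted_mean_metric(c(1.0, 0.5), c(10, 5)), 0.8333333, tolerance = 1e-6)
  expect_equal(weighted_mean_metric(rep(0.7, 4), c(1, 9, 3, 2)), 0.7)
  expect_equal(weighted_mean_metric(0.42, 3), 0.42)
  expect_error(weighted_mean_metric(1:2, 1:3), "length")
})

test_that("correlation metrics capture rank-ordering ability", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(kendall_tau(x, 2 * x + 1), 1)
  expect_equal(kendall_tau(x, rev(x)), -1)
  # brute-force concordant/discordant count: (5 - 1) / 6
  expect_equal(kendall_tau(x, c(1, 3, 2, 4)), 2 / 3)
  # offset and scale invariance of R^2
  set.seed(19)
  a <- rnorm(20); b <- a + rnorm(20, sd = 0.4)
  expect_equal(r_squared(a, b), r_squared(a, 3 * b - 7))
  expect_error(r_squared(a, rep(1, 20)), "zero variance")
  expect_error(kendall_tau(a, rep(1, 20)), "zero variance")
})

test_that("comparison_metrics assembles the full suite with invariants", {
  set.seed(23)
  pred <- rnorm(10, -10); exp <- pred + rnorm(10, sd = 0.3)
  m <- comparison_metrics(pred, exp, label = "fixture")
  expect_s3_class(m, "comparison_metrics")
  expect_gte(m$pairwise_rmse, m$pairwise_mue)
  expect_true(m$r_squared >= 0 && m$r_squared <= 1)
  expect_true(m$kendall_tau >= -1 && m$kendall_tau <= 1)
  expect_equal(m$n_compounds, 10)
  expect_true(is.na(m$edgewise_rmse))
  # with a graph attached, edgewise fields appear
  sim <- simulate_graph(graph_sim_config(n_nodes = 10, extra_cycle_edges = 3, seed = 5))
  nd <- infer_node_dgs(sim$graph)
  m2 <- comparison_metrics(
    nd$dg, sim$truth$dg_true,
    graph = sim$graph
  )
  expect_false(is.na(m2$edgewise_rmse))
  expect_equal(m2$n_edges, nrow(sim$graph$edges))
})

test_that("bootstrap CI is deterministic, degenerate for M = 1, and ordered", {
  one <- bootstrap_ci(0.9, 12, n_boot = 200, seed = 1)
  expect_equal(one$point, 0.9)
  expect_equal(one$ci_low, 0.9)
  expect_equal(one$ci_high, 0.9)
  same <- bootstrap_ci(rep(1.1, 6), rep(4, 6), n_boot = 200, seed = 2)
  expect_equal(same$ci_low, same$ci_high)
  vals <- c(0.8, 1.4, 0.6, 1.0)
  w <- c(10, 40, 5, 12)
  r1 <- bootstrap_ci(vals, w, n_boot = 500, seed = 7)
  r2 <- bootstrap_ci(vals, w, n_boot = 500, seed = 7)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, r1$ci_high)
  expect_error(bootstrap_ci(vals, w, n_boot = 100), "seed")
  expect_error(bootstrap_ci(numeric(0), numeric(0), seed = 1), "non-empty")
  # weighted_mean statistic point estimate matches the direct computation
  rm_ <- bootstrap_ci(vals, w, statistic = "weighted_mean", n_boot = 100, seed = 3)
  expect_equal(rm_$point, weighted_mean_metric(vals, w))
})
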