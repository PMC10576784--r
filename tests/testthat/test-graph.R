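test_that("noiseless chain is reproduced exactly and mean-centered", {
  nd <- infer_node_dgs(chain_graph())
  expect_equal(nd$dg[match(c("a", "b", "c"), nd$compound_id)], c(1, 0, -1))
  expect_equal(mean(nd$dg), 0)
  fitted <- consistent_edge_ddgs(nd, chain_graph())
  expect_equal(fitted$ddg_fit, fitted$ddg_pred)
})

test_that("inconsistent triangle gives the hand-solved least-squares fit", {
  g <- triangle_graph()
  nd <- infer_node_dgs(g)
  fitted <- consistent_edge_ddgs(nd, g)
  # solved by hand from the 2x2 normal equations: x = y = 1.1
  expect_equal(fitted$ddg_fit, c(1.1, 1.1, 2.2))
  # cycle closure: signed sum around the triangle is zero
  expect_equal(fitted$ddg_fit[1] + fitted$ddg_fit[2] - fitted$ddg_fit[3], 0)
  expect_equal(mean(nd$dg), 0)
})

test_that("fitted node dGs minimize the weighted least-squares objective", {
  set.seed(42)
  sim <- simulate_graph(graph_sim_config(
    n_nodes = 12, extra_cycle_edges = 8, edge_noise_sd = 0.5, seed = 9
  ))
  nd <- infer_node_dgs(sim$graph)
  dg <- stats::setNames(nd$dg, nd$compound_id)
  f0 <- wls_objective(dg, sim$graph)
  for (i in 1:1000) {
    perturbed <- dg + rnorm(length(dg), sd = 0.05)
    expect_gte(wls_objective(perturbed, sim$graph), f0)
  }
})

test_that("zero-noise graphs recover true mean-centered dGs to < 1e-8", {
  for (seed in 1:5) {
    sim <- simulate_graph(graph_sim_config(
      n_nodes = 25, extra_cycle_edges = 15, edge_noise_sd = 0, seed = seed
    ))
    nd <- infer_node_dgs(sim$graph)
    truth <- sim$truth$dg_true[match(nd$compound_id, sim$truth$compound_id)]
    expect_lt(max(abs(nd$dg - (truth - mean(truth)))), 1e-8)
  }
})

test_that("cycle sums of fitted edges vanish on noisy cyclic graphs", {
  sim <- simulate_graph(graph_sim_config(
    n_nodes = 15, extra_cycle_edges = 10, edge_noise_sd = 0.8, seed = 4
  ))
  nd <- infer_node_dgs(sim$graph)
  fitted <- consistent_edge_ddgs(nd, sim$graph)
  # every cycle sum vanishes because fitted edges are differences of node
  # potentials; check all triangles present in the edge set
  dg <- stats::setNames(nd$dg, nd$compound_id)
  key <- paste(fitted$ligand_a, fitted$ligand_b)
  val <- stats::setNames(fitted$ddg_fit, key)
  ids <- nd$compound_id
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      for (k in seq_along(ids)) {
        e1 <- val[paste(ids[i], ids[j])]
        e2 <- val[paste(ids[j], ids[k])]
        e3 <- val[paste(ids[i], ids[k])]
        if (!anyNA(c(e1, e2, e3))) {
          expect_equal(unname(e1 + e2 - e3), 0, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("spanning-tree inference reproduces path-summed ddGs exactly", {
  sim <- simulate_graph(graph_sim_config(
    n_nodes = 10, extra_cycle_edges = 0, edge_noise_sd = 0.7, seed = 2
  ))
  nd <- infer_node_dgs(sim$graph)
  fitted <- consistent_edge_ddgs(nd, sim$graph)
  # no cycles: nothing to correct, fitted edges equal the noisy inputs
  expect_equal(fitted$ddg_fit, fitted$ddg_pred, tolerance = 1e-10)
})

test_that("weighted inference with equal SEs equals unweighted inference", {
  g <- triangle_graph()
  g_se <- perturbation_graph(transform(as.data.frame(g$edges[1:3]), ddg_se = 0.3))
  expect_equal(infer_node_dgs(g_se)$dg, infer_node_dgs(g)$dg, tolerance = 1e-10)
})

test_that("mixed SE presence falls back to unit weights with a warning", {
  edges <- data.frame(
    ligand_a = c("a", "b", "a"), ligand_b = c("b", "c", "c"),
    ddg_pred = c(1, 1, 2.3), ddg_se = c(0.2, NA, 0.2)
  )
  expect_warning(nd <- infer_node_dgs(perturbation_graph(edges)), "unit weights")
  expect_equal(nd$dg, infer_node_dgs(triangle_graph())$dg)
})

test_that("unequal edge weights pull the fit toward the precise edges", {
  edges <- data.frame(
    ligand_a = c("a", "b", "a"), ligand_b = c("b", "c", "c"),
    ddg_pred = c(1, 1, 2.3), ddg_se = c(0.1, 0.1, 1.0)
  )
  nd <- infer_node_dgs(perturbation_graph(edges))
  fitted <- consistent_edge_ddgs(nd, perturbation_graph(edges))
  # precise edges should sit closer to their predictions than in the
  # unweighted fit (where all residuals were 0.1)
  expect_lt(abs(fitted$residual[1]), 0.1)
  expect_lt(abs(fitted$residual[2]), 0.1)
  expect_gt(abs(fitted$residual[3]), 0.1)
})

test_that("node SEs vanish exactly when the graph closes perfectly", {
  sim <- simulate_graph(graph_sim_config(
    n_nodes = 8, extra_cycle_edges = 5, edge_noise_sd = 0, seed = 3
  ))
  nd <- infer_node_dgs(sim$graph)
  expect_equal(nd$dg_se, rep(0, nrow(nd)), tolerance = 1e-8)
})

test_that("graph validation rejects malformed and disconnected inputs", {
  expect_error(
    perturbation_graph(data.frame(ligand_a = "a", ligand_b = "a", ddg_pred = 1)),
    "self-edges"
  )
  expect_error(
    perturbation_graph(data.frame(ligand_a = character(), ligand_b = character(), ddg_pred = numeric())),
    "at least one edge"
  )
  disconnected <- perturbation_graph(data.frame(
    ligand_a = c("a", "c"), ligand_b = c("b", "d"), ddg_pred = c(1, 1)
  ))
  expect_error(infer_node_dgs(disconnected), "disconnected")
  nd <- infer_node_dgs(chain_graph())
  expect_error(consistent_edge_ddgs(nd[1:2, ], chain_graph()), "missing")
})

test_that("duplicate edges act as independent repeat observations", {
  base <- data.frame(
    ligand_a = c("a", "b", "a"), ligand_b = c("b", "c", "c"),
    ddg_pred = c(1, 1, 2.3)
  )
  doubled <- rbind(base, base[3, ]) # repeat the diagonal edge
  nd1 <- infer_node_dgs(perturbation_graph(base))
  nd2 <- infer_node_dgs(perturbation_graph(doubled))
  f1 <- consistent_edge_ddgs(nd1, perturbation_graph(base))
  f2 <- consistent_edge_ddgs(nd2, perturbation_graph(doubled))
  # the repeated edge gains effective weight, so its fit moves toward 2.3
  expect_gt(f2$ddg_fit[3], f1$ddg_fit[3])
})

test_that("mean alignment shifts predictions without touching relative metrics", {
  expect_equal(align_offset(c(1, 2, 3), c(2, 3, 4)), c(2, 3, 4))
  set.seed(7)
  pred <- rnorm(5)
  exp <- rnorm(5)
  shifted <- align_offset(pred, exp)
  expect_equal(mean(shifted), mean(exp))
  expect_equal(rmse(pairwise_errors(shifted, exp)), rmse(pairwise_errors(pred, exp)))
  expect_equal(kendall_tau(shifted, exp), kendall_tau(pred, exp))
  expect_error(align_offset(1:3, 1:2), "equal length")
})

test_that("inference ignores experimental dGs attached to nodes", {
  edges <- data.frame(ligand_a = c("a", "b"), ligand_b = c("b", "c"), ddg_pred = c(1, 1))
  g1 <- perturbation_graph(edges, exp_dg = c(a = -10, b = -11, c = -12))
  g2 <- perturbation_graph(edges, exp_dg = c(a = -5, b = -6, c = -7))
  expect_equal(infer_node_dgs(g1)$dg, infer_node_dgs(g2)$dg)
})
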