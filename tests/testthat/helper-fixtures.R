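# Shared fixtures and independent oracles used across test files.

kT300 <- 1.9872e-3 * 300

# brute-force all-pairs oracle: loop over every unordered pair explicitly
brute_force_pairwise <- function(pred, exp) {
  n <- length(pred)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- c(out, (pred[i] - pred[j]) - (exp[i] - exp[j]))
    }
  }
  out
}

# the hand-solved inconsistent triangle: a->b 1.0, b->c 1.0, a->c 2.3
triangle_graph <- function() {
  perturbation_graph(data.frame(
    ligand_a = c("a", "b", "a"),
    ligand_b = c("b", "c", "c"),
    ddg_pred = c(1.0, 1.0, 2.3)
  ))
}

chain_graph <- function() {
  perturbation_graph(data.frame(
    ligand_a = c("a", "b"),
    ligand_b = c("b", "c"),
    ddg_pred = c(1.0, 1.0)
  ))
}

# minimal two-assay fixture over shared compounds, values in molar
make_series <- function(values, ids = sprintf("c%02d", seq_along(values)),
                        assay_id = "assay", category = "binding",
                        measure_type = "Ki", qualifier = "eq") {
  assay_series(
    data.frame(
      compound_id = ids,
      measure_type = measure_type,
      value_molar = values,
      qualifier = qualifier
    ),
    assay_id = assay_id, category = category
  )
}

# weighted least-squares objective for graph inference
wls_objective <- function(dg_named, g, weights = rep(1, nrow(g$edges))) {
  d <- dg_named[g$edges$ligand_a] - dg_named[g$edges$ligand_b]
  sum(weights * (d - g$edges$ddg_pred)^2)
}

expect_tibble_equal_num <- function(x, y, tol = 1e-12) {
  expect_equal(as.data.frame(x), as.data.frame(y), tolerance = tol)
}
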