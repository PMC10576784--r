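#' Configuration for simulating a pair of assay series
#'
#' Describes a congeneric series measured by two assays: true binding free
#' energies drawn once, then per-assay additive offsets, per-assay noise
#' (Gaussian or Student-t, applied on the dG scale, consistent with
#' log-concentration measurement error), and optional detection-limit
#' censoring on the concentration scale.
#'
#' @param n_compounds Number of compounds in the series (>= 2).
#' @param dg_range Dynamic range of true dG values in kcal mol^-1: the span
#'   of a uniform distribution (`dg_dist = "uniform"`, the default, 5
#'   kcal/mol as typical for a congeneric series) or the standard deviation
#'   (`dg_dist = "normal"`).
#' @param dg_center Center of the true dG distribution, kcal mol^-1.
#'   Default -10 (roughly 50 nM affinities at 300 K).
#' @param dg_dist `"uniform"` or `"normal"`.
#' @param assay_offsets Length-2 numeric: additive dG shift of each assay
#'   (systematic inter-assay offset, irrelevant for relative metrics).
#' @param noise List of two per-assay noise models, each
#'   `list(model = "gaussian", sd = ...)` or
#'   `list(model = "student_t", df = ..., scale = ...)`.
#' @param censor_limits List of two per-assay limits, each `NULL` or
#'   `c(lower, upper)` molar concentration bounds; measured values outside
#'   are clamped to the limit and flagged `"lt"` / `"gt"`.
#' @param measure_types Length-2 character, per-assay measure type.
#' @param categories Length-2 character, per-assay category
#'   (`"binding"`/`"functional"`).
#' @param seed Integer seed; the same config and seed give bit-identical
#'   output.
#' @return A list of class `series_sim_config`.
#' @export
series_sim_config <- function(n_compounds = 50L,
                              dg_range = 5,
                              dg_center = -10,
                              dg_dist = c("uniform", "normal"),
                              assay_offsets = c(0, 0),
                              noise = list(
                                list(model = "gaussian", sd = 0.6),
                                list(model = "gaussian", sd = 0.6)
                              ),
                              censor_limits = list(NULL, NULL),
                              measure_types = c("Ki", "Ki"),
                              categories = c("binding", "functional"),
                              seed = 1L) {
  dg_dist <- match.arg(dg_dist)
  stopifnot(
    n_compounds >= 2L, dg_range > 0,
    length(assay_offsets) == 2L, length(noise) == 2L,
    length(censor_limits) == 2L, length(measure_types) == 2L,
    length(categories) == 2L
  )
  for (nm in noise) {
    stopifnot(nm$model %in% c("gaussian", "student_t"))
    if (nm$model == "gaussian") stopifnot(nm$sd > 0 || nm$sd == 0)
    if (nm$model == "student_t") stopifnot(nm$df > 0, nm$scale > 0)
  }
  structure(
    list(
      n_compounds = as.integer(n_compounds), dg_range = dg_range,
      dg_center = dg_center, dg_dist = dg_dist,
      assay_offsets = assay_offsets, noise = noise,
      censor_limits = censor_limits, measure_types = measure_types,
      categories = categories, seed = as.integer(seed)
    ),
    class = "series_sim_config"
  )
}

draw_noise <- function(n, model) {
  switch(model$model,
    gaussian = if (model$sd == 0) rep(0, n) else stats::rnorm(n, sd = model$sd),
    student_t = model$scale * stats::rt(n, df = model$df)
  )
}

#' Simulate a congeneric series measured by two assays
#'
#' Draws true dG values once, measures them in two assays (offset + noise on
#' the dG scale), back-transforms to molar concentrations via
#' `X = exp(dG / kT)`, and applies detection-limit censoring by clamping to
#' the limit with a `"lt"`/`"gt"` qualifier. The truth record keeps the
#' uncensored values so generator output can serve as a test oracle.
#'
#' @param cfg A [series_sim_config()].
#' @param constants A [thermo_constants()] object.
#' @return A list with `truth` (tibble: `compound_id`, `dg_true`,
#'   `dg_measured_a`, `dg_measured_b` -- uncensored), and `series`, a list of
#'   two [assay_series()] (`$a`, `$b`).
#' @export
simulate_assay_pair <- function(cfg, constants = thermo_constants()) {
  stopifnot(inherits(cfg, "series_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_compounds
    ids <- sprintf("cpd-%03d", seq_len(n))
    dg_true <- switch(cfg$dg_dist,
      uniform = stats::runif(n, cfg$dg_center - cfg$dg_range / 2, cfg$dg_center + cfg$dg_range / 2),
      normal = stats::rnorm(n, cfg$dg_center, cfg$dg_range)
    )
    measured <- lapply(1:2, function(k) {
      dg_true + cfg$assay_offsets[k] + draw_noise(n, cfg$noise[[k]])
    })
    series <- lapply(1:2, function(k) {
      x <- exp(measured[[k]] / constants$kT)
      qualifier <- rep("eq", n)
      lim <- cfg$censor_limits[[k]]
      if (!is.null(lim)) {
        stopifnot(length(lim) == 2L, lim[1] < lim[2])
        below <- x < lim[1]
        above <- x > lim[2]
        x[below] <- lim[1]
        x[above] <- lim[2]
        qualifier[below] <- "lt"
        qualifier[above] <- "gt"
      }
      assay_series(
        tibble::tibble(
          compound_id = ids,
          measure_type = cfg$measure_types[k],
          value_molar = x,
          qualifier = qualifier
        ),
        assay_id = sprintf("sim-assay-%s", c("a", "b")[k]),
        category = cfg$categories[k],
        source_tag = "synthetic"
      )
    })
    list(
      truth = tibble::tibble(
        compound_id = ids,
        dg_true = dg_true,
        dg_measured_a = measured[[1]],
        dg_measured_b = measured[[2]]
      ),
      series = stats::setNames(series, c("a", "b"))
    )
  })
}

#' Configuration for simulating a perturbation graph
#'
#' A connected graph built as a uniform random spanning tree plus a given
#' number of extra cycle-closing chords, with edge ddG predictions equal to
#' the true node dG differences plus Gaussian noise.
#'
#' @param n_nodes Number of ligands (>= 2).
#' @param extra_cycle_edges Chords beyond the spanning tree (0 gives a
#'   tree); bounded by `n_nodes*(n_nodes-1)/2 - (n_nodes-1)`.
#' @param edge_noise_sd Standard deviation of edge prediction noise
#'   (kcal mol^-1, >= 0).
#' @param edge_se_reported If `TRUE`, edges carry `ddg_se = edge_noise_sd`.
#' @param dg_range,dg_center True-dG uniform span and center (kcal mol^-1).
#' @param seed Integer seed.
#' @return A list of class `graph_sim_config`.
#' @export
graph_sim_config <- function(n_nodes = 20L, extra_cycle_edges = 10L,
                             edge_noise_sd = 0.4, edge_se_reported = FALSE,
                             dg_range = 5, dg_center = -10, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  extra_cycle_edges <- as.integer(extra_cycle_edges)
  stopifnot(n_nodes >= 2L, edge_noise_sd >= 0, dg_range > 0)
  max_extra <- (n_nodes * (n_nodes - 1L)) %/% 2L - (n_nodes - 1L)
  if (extra_cycle_edges < 0L || extra_cycle_edges > max_extra) {
    stop("`extra_cycle_edges` must be between 0 and ", max_extra, call. = FALSE)
  }
  structure(
    list(
      n_nodes = n_nodes, extra_cycle_edges = extra_cycle_edges,
      edge_noise_sd = edge_noise_sd, edge_se_reported = edge_se_reported,
      dg_range = dg_range, dg_center = dg_center, seed = as.integer(seed)
    ),
    class = "graph_sim_config"
  )
}

#' Simulate a perturbation graph with noisy edge predictions
#'
#' @param cfg A [graph_sim_config()].
#' @return A list with `truth` (tibble `compound_id`, `dg_true`), `graph`
#'   (a [perturbation_graph()] whose nodes carry the exact experimental dG),
#'   and `exp_dg` (named vector of the true dG values).
#' @export
simulate_graph <- function(cfg) {
  stopifnot(inherits(cfg, "graph_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_nodes
    ids <- sprintf("lig-%03d", seq_len(n))
    dg_true <- stats::runif(n, cfg$dg_center - cfg$dg_range / 2, cfg$dg_center + cfg$dg_range / 2)

    # random spanning tree: each node attaches to a uniformly chosen predecessor
    tree <- if (n > 1L) {
      cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
    } else {
      matrix(integer(0), ncol = 2)
    }
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE) # j > i columns
    pair_key <- function(i, j) pmin(i, j) * (n + 1L) + pmax(i, j)
    tree_keys <- pair_key(tree[, 1], tree[, 2])
    chord_pool <- all_pairs[!pair_key(all_pairs[, 1], all_pairs[, 2]) %in% tree_keys, , drop = FALSE]
    chords <- if (cfg$extra_cycle_edges > 0L) {
      chord_pool[sample.int(nrow(chord_pool), cfg$extra_cycle_edges), , drop = FALSE]
    } else {
      matrix(integer(0), ncol = 2)
    }
    em <- rbind(tree, chords)
    noise <- if (cfg$edge_noise_sd > 0) {
      stats::rnorm(nrow(em), sd = cfg$edge_noise_sd)
    } else {
      rep(0, nrow(em))
    }
    edges <- tibble::tibble(
      ligand_a = ids[em[, 1]],
      ligand_b = ids[em[, 2]],
      ddg_pred = dg_true[em[, 1]] - dg_true[em[, 2]] + noise,
      ddg_se = if (cfg$edge_se_reported) rep(cfg$edge_noise_sd, nrow(em)) else NA_real_
    )
    exp_dg <- stats::setNames(dg_true, ids)
    list(
      truth = tibble::tibble(compound_id = ids, dg_true = dg_true),
      graph = perturbation_graph(edges, exp_dg = exp_dg),
      exp_dg = exp_dg
    )
  })
}
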