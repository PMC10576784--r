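#' Construct an assay series
#'
#' One assay's affinity measurements over a congeneric ligand series,
#' together with assay metadata. Measurements are stored in molar units with
#' a censoring qualifier: `"eq"` for an in-range value, `"lt"`/`"gt"` for a
#' value reported only as below/above a detection limit.
#'
#' @param measurements Data frame with columns `compound_id`,
#'   `measure_type` (`"Kd"`, `"Ki"` or `"IC50"`), `value_molar` (> 0),
#'   and optionally `qualifier` (default `"eq"`) and `std_err`.
#' @param assay_id Identifier for the assay.
#' @param category `"binding"` (direct binding readout, e.g. SPR or ITC) or
#'   `"functional"` (activity inhibition readout).
#' @param source_tag Provenance label: `"public"`, `"internal"` or
#'   `"synthetic"`.
#' @return An object of class `assay_series`.
#' @export
assay_series <- function(measurements, assay_id,
                         category = c("binding", "functional"),
                         source_tag = c("synthetic", "public", "internal")) {
  category <- match.arg(category)
  source_tag <- match.arg(source_tag)
  m <- tibble::as_tibble(measurements)
  required <- c("compound_id", "measure_type", "value_molar")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    stop("measurements lack columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"qualifier" %in% names(m)) m$qualifier <- "eq"
  if (!"std_err" %in% names(m)) m$std_err <- NA_real_
  m$compound_id <- as.character(m$compound_id)
  if (anyDuplicated(m$compound_id)) {
    stop("duplicate compound_id within assay '", assay_id, "'", call. = FALSE)
  }
  if (!all(m$measure_type %in% valid_measure_types)) {
    bad <- setdiff(unique(m$measure_type), valid_measure_types)
    stop("unknown measure_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(m$value_molar) || any(m$value_molar <= 0)) {
    stop("value_molar must be strictly positive", call. = FALSE)
  }
  if (!all(m$qualifier %in% valid_qualifiers)) {
    stop("qualifier must be one of ", paste(valid_qualifiers, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      assay_id = as.character(assay_id),
      category = category,
      source_tag = source_tag,
      measurements = m[c("compound_id", "measure_type", "value_molar", "qualifier", "std_err")]
    ),
    class = "assay_series"
  )
}

#' @export
print.assay_series <- function(x, ...) {
  cat(sprintf(
    "<assay_series> '%s' (%s, %s): %d compounds, %d censored\n",
    x$assay_id, x$category, x$source_tag, nrow(x$measurements),
    sum(x$measurements$qualifier != "eq")
  ))
  invisible(x)
}

#' Match compounds measured by two assays
#'
#' Inner join on compound id, in canonical (sorted) order, so both assays'
#' measurements of each shared compound sit side by side.
#'
#' @param a,b [assay_series()] objects over (partially) shared compounds.
#' @return Tibble with one row per shared compound: `compound_id` plus
#'   `_a` / `_b` suffixed measurement columns.
#' @export
match_compounds <- function(a, b) {
  stopifnot(inherits(a, "assay_series"), inherits(b, "assay_series"))
  pairs <- dplyr::inner_join(
    a$measurements, b$measurements,
    by = "compound_id", suffix = c("_a", "_b")
  )
  pairs <- dplyr::arrange(pairs, .data$compound_id)
  if (nrow(pairs) < 2L) {
    stop(
      "assays '", a$assay_id, "' and '", b$assay_id,
      "' share fewer than 2 compounds",
      call. = FALSE
    )
  }
  pairs
}

#' Remove detection-limit-censored compound pairs
#'
#' Values at an assay's detection limit show up as vertical or horizontal
#' lines in an assay-vs-assay scatter plot and carry no relative-affinity
#' information. Two policies are available:
#' * `"qualifier_only"`: drop a pair when either measurement's qualifier is
#'   `"lt"` or `"gt"`.
#' * `"qualifier_plus_plateau"`: additionally drop pairs where one assay's
#'   value equals that assay's minimum or maximum among the matched pairs
#'   and at least `plateau_k` compounds share that extreme value (an
#'   unflagged plateau at an assay limit).
#'
#' @param pairs Matched-pair tibble from [match_compounds()].
#' @param policy Censoring policy; see above.
#' @param plateau_k Minimum number of compounds sharing an extreme value for
#'   the plateau rule to trigger (default 3).
#' @return A list with `pairs` (retained rows) and `removed` (a log tibble
#'   with `compound_id` and `reason` for every dropped pair).
#' @export
censor_filter <- function(pairs, policy = c("qualifier_only", "qualifier_plus_plateau"),
                          plateau_k = 3L) {
  policy <- match.arg(policy)
  reason <- rep(NA_character_, nrow(pairs))
  flagged <- pairs$qualifier_a != "eq" | pairs$qualifier_b != "eq"
  reason[flagged] <- "censoring qualifier"
  if (policy == "qualifier_plus_plateau") {
    for (side in c("a", "b")) {
      v <- pairs[[paste0("value_molar_", side)]]
      for (extreme in c(min(v), max(v))) {
        at <- v == extreme
        if (sum(at) >= plateau_k) {
          reason[at & is.na(reason)] <- sprintf("plateau at assay %s limit", side)
        }
      }
    }
  }
  keep <- is.na(reason)
  removed <- tibble::tibble(
    compound_id = pairs$compound_id[!keep],
    reason = reason[!keep]
  )
  if (!any(keep)) {
    warning("all pairs removed by censoring filter", call. = FALSE)
  }
  list(pairs = pairs[keep, , drop = FALSE], removed = removed)
}

comparison_category <- function(cat_a, cat_b) {
  cats <- sort(c(cat_a, cat_b))
  paste(cats[1], "vs", cats[2])
}

#' Compare relative binding free energies between two assays
#'
#' The reproducibility comparison for one assay pair: match compounds,
#' apply the censoring filter, convert each assay's affinities to dG values,
#' and compute the pairwise error metrics (RMSE, MUE, squared Pearson
#' correlation, Kendall tau-b). All metrics are invariant to the per-assay
#' additive constant, so assays reporting different measure types can be
#' compared.
#'
#' @param a,b [assay_series()] objects.
#' @param policy,plateau_k Censoring policy, see [censor_filter()].
#' @param constants A [thermo_constants()] object.
#' @return An object of class `assay_comparison`: list with `metrics`
#'   (a [comparison_metrics()] row), `shared_compounds`, `removed` (censor
#'   log), `comparison_category`, `dg` (per-compound dG tibble), and the
#'   two assay ids.
#' @export
compare_assays <- function(a, b, policy = "qualifier_only", plateau_k = 3L,
                           constants = thermo_constants()) {
  pairs <- match_compounds(a, b)
  cens <- censor_filter(pairs, policy = policy, plateau_k = plateau_k)
  kept <- cens$pairs
  if (nrow(kept) < 2L) {
    stop(
      "fewer than 2 uncensored shared compounds between '",
      a$assay_id, "' and '", b$assay_id, "'",
      call. = FALSE
    )
  }
  dg_a <- abs_dg(kept$value_molar_a, constants)
  dg_b <- abs_dg(kept$value_molar_b, constants)
  metrics <- comparison_metrics(
    dg_a, dg_b,
    label = paste(a$assay_id, "vs", b$assay_id)
  )
  structure(
    list(
      assay_a = a$assay_id,
      assay_b = b$assay_id,
      comparison_category = comparison_category(a$category, b$category),
      shared_compounds = kept$compound_id,
      removed = cens$removed,
      dg = tibble::tibble(
        compound_id = kept$compound_id, dg_a = dg_a, dg_b = dg_b
      ),
      metrics = metrics
    ),
    class = "assay_comparison"
  )
}

#' @export
print.assay_comparison <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0(
      "<assay_comparison> %s (%s)\n",
      "  %d shared compounds (%d removed by censoring)\n",
      "  pairwise RMSE %.2f, MUE %.2f kcal/mol; R^2 %.2f, tau %.2f\n"
    ),
    m$label, x$comparison_category, m$n_compounds, nrow(x$removed),
    m$pairwise_rmse, m$pairwise_mue, m$r_squared, m$kendall_tau
  ))
  invisible(x)
}

#' Aggregate assay comparisons into survey-level summaries
#'
#' Aggregates per-comparison metrics into overall and per-category
#' reproducibility estimates. RMSE is aggregated with the weighted quadratic
#' mean ([weighted_rmse()]); MUE, R-squared and Kendall tau with the linear
#' weighted mean. Weights are the shared-compound counts. 95% confidence
#' intervals come from percentile bootstrap over whole comparisons.
#'
#' @param comparisons A list of [compare_assays()] results.
#' @param n_boot Bootstrap replicates per interval.
#' @param seed Integer seed for the bootstrap.
#' @return A list with `comparisons` (flat per-comparison metric tibble,
#'   incl. `comparison_category` and `weight`) and `summary` (one row per
#'   metric and category -- categories plus `"overall"` -- with `point`,
#'   `ci_low`, `ci_high`, `M`).
#' @export
survey_aggregate <- function(comparisons, n_boot = 10000L, seed) {
  if (length(comparisons) < 1L) stop("no comparisons to aggregate", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(all(vapply(comparisons, inherits, TRUE, "assay_comparison")))
  flat <- dplyr::bind_rows(lapply(comparisons, function(cmp) {
    dplyr::mutate(cmp$metrics,
      comparison_category = cmp$comparison_category,
      weight = cmp$metrics$n_compounds
    )
  }))
  metric_cols <- c(
    pairwise_rmse = "weighted_rmse",
    pairwise_mue = "weighted_mean",
    r_squared = "weighted_mean",
    kendall_tau = "weighted_mean"
  )
  groups <- c(stats::setNames(unique(flat$comparison_category), unique(flat$comparison_category)),
    overall = "overall"
  )
  rows <- list()
  i <- 0L
  for (grp in names(groups)) {
    sub <- if (grp == "overall") flat else flat[flat$comparison_category == grp, ]
    for (metric in names(metric_cols)) {
      vals <- sub[[metric]]
      ok <- !is.na(vals)
      if (!any(ok)) next
      i <- i + 1L
      ci <- bootstrap_ci(
        vals[ok], sub$weight[ok],
        statistic = metric_cols[[metric]],
        n_boot = n_boot, seed = seed + i
      )
      rows[[i]] <- tibble::tibble(
        category = grp, metric = metric,
        point = ci$point, ci_low = ci$ci_low, ci_high = ci$ci_high,
        M = sum(ok), total_weight = sum(sub$weight[ok])
      )
    }
  }
  list(comparisons = flat, summary = dplyr::bind_rows(rows))
}

#' Root-mean-square of reported repeatability standard deviations
#'
#' Summarizes per-compound standard deviations reported from repeat
#' measurements: the RMS over all compounds, with a bootstrap confidence
#' interval obtained by resampling whole assay groups (not individual
#' compounds). Feeding the result to [abs_rmse_to_pairwise_rmse()] gives the
#' repeatability contribution to a two-measurement difference.
#'
#' @param sds Data frame with columns `assay_id` and `sd` (reported
#'   standard deviations in kcal mol^-1, >= 0).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return A one-row tibble: `point`, `ci_low`, `ci_high`, `n_compounds`,
#'   `n_assays`.
#' @export
repeatability_rms <- function(sds, n_boot = 10000L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sds <- tibble::as_tibble(sds)
  stopifnot(all(c("assay_id", "sd") %in% names(sds)))
  if (nrow(sds) < 1L) stop("no standard deviations supplied", call. = FALSE)
  if (anyNA(sds$sd) || any(sds$sd < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  groups <- split(sds$sd, sds$assay_id)
  point <- sqrt(mean(sds$sd^2))
  reps <- withr::with_seed(seed, {
    k <- length(groups)
    vapply(seq_len(n_boot), function(i) {
      pick <- sample.int(k, k, replace = TRUE)
      sqrt(mean(unlist(groups[pick], use.names = FALSE)^2))
    }, 0)
  })
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  tibble::tibble(
    point = point, ci_low = ci[1], ci_high = ci[2],
    n_compounds = nrow(sds), n_assays = length(groups)
  )
}
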