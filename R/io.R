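#' Read and write assay CSV files
#'
#' The assay CSV dialect is a plain CSV with columns `compound_id`,
#' `measure_type`, `value`, `qualifier`, `std_err`, preceded by
#' `#key: value` metadata lines carrying `assay_id`, `category`,
#' `source_tag` and `value_units`. Supported unit dialects: `molar`,
#' `nanomolar`, and `pKi` (value is the pKi; converted to molar as
#' `10^-pKi` on ingest). Values are always stored internally in molar
#' units, so downstream free-energy math never mixes unit scales.
#'
#' @param path File path.
#' @return `read_assay_csv()` returns an [assay_series()];
#'   `write_assay_csv()` returns `path` invisibly.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- read_hash_metadata(path)
  for (key in c("assay_id", "category", "value_units")) {
    if (is.null(meta[[key]])) {
      stop("assay CSV '", path, "' lacks metadata line '#", key, ":'", call. = FALSE)
    }
  }
  units <- meta$value_units
  if (!units %in% c("molar", "nanomolar", "pKi")) {
    stop("unknown value_units dialect: ", units, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("compound_id", "measure_type", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("assay CSV lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"qualifier" %in% names(df)) df$qualifier <- "eq"
  df$qualifier[is.na(df$qualifier) | df$qualifier == ""] <- "eq"
  if (!"std_err" %in% names(df)) df$std_err <- NA_real_
  validate_rows(df, path, units)
  value_molar <- switch(units,
    molar = df$value,
    nanomolar = df$value * 1e-9,
    pKi = 10^(-df$value)
  )
  assay_series(
    tibble::tibble(
      compound_id = df$compound_id,
      measure_type = df$measure_type,
      value_molar = value_molar,
      qualifier = df$qualifier,
      std_err = as.numeric(df$std_err)
    ),
    assay_id = meta$assay_id,
    category = meta$category,
    source_tag = meta$source_tag %||% "public"
  )
}

validate_rows <- function(df, path, units) {
  # row numbers reported relative to the data (header = row 0)
  bad_type <- which(!df$measure_type %in% valid_measure_types)
  if (length(bad_type) > 0L) {
    stop("row ", bad_type[1], " of '", path, "': unknown measure_type '",
      df$measure_type[bad_type[1]], "'",
      call. = FALSE
    )
  }
  v <- suppressWarnings(as.numeric(df$value))
  bad_val <- which(is.na(v) | (units != "pKi" & v <= 0))
  if (length(bad_val) > 0L) {
    stop("row ", bad_val[1], " of '", path, "': value must be a positive concentration",
      call. = FALSE
    )
  }
  bad_q <- which(!df$qualifier %in% valid_qualifiers)
  if (length(bad_q) > 0L) {
    stop("row ", bad_q[1], " of '", path, "': qualifier must be eq/lt/gt",
      call. = FALSE
    )
  }
  dup <- which(duplicated(df$compound_id))
  if (length(dup) > 0L) {
    stop("row ", dup[1], " of '", path, "': duplicate compound_id '",
      df$compound_id[dup[1]], "'",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

read_hash_metadata <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_assay_csv
#' @param series An [assay_series()] to write.
#' @param value_units Output dialect: `"molar"`, `"nanomolar"` or `"pKi"`.
#' @export
write_assay_csv <- function(series, path, value_units = "molar") {
  stopifnot(inherits(series, "assay_series"))
  if (!value_units %in% c("molar", "nanomolar", "pKi")) {
    stop("unknown value_units dialect: ", value_units, call. = FALSE)
  }
  m <- series$measurements
  value <- switch(value_units,
    molar = m$value_molar,
    nanomolar = m$value_molar / 1e-9,
    pKi = -log10(m$value_molar)
  )
  out <- data.frame(
    compound_id = m$compound_id,
    measure_type = m$measure_type,
    value = format(value, digits = 17, scientific = TRUE, trim = TRUE),
    qualifier = m$qualifier,
    std_err = m$std_err
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#assay_id: ", series$assay_id),
    paste0("#category: ", series$category),
    paste0("#source_tag: ", series$source_tag),
    paste0("#value_units: ", value_units)
  ), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write perturbation-graph edge lists
#'
#' Edge-list CSV with columns `ligand_a`, `ligand_b`, `ddg_pred` and
#' optional `ddg_se` (kcal mol^-1). Experimental dG values can be joined
#' from an assay CSV by compound id.
#'
#' @param path Edge-list CSV path.
#' @param assay_path Optional assay CSV whose affinities provide
#'   experimental dG values for the graph nodes.
#' @param constants A [thermo_constants()] object for the dG conversion.
#' @return `read_graph_csv()` returns a [perturbation_graph()];
#'   `write_graph_csv()` returns `path` invisibly.
#' @export
read_graph_csv <- function(path, assay_path = NULL, constants = thermo_constants()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  exp_dg <- NULL
  if (!is.null(assay_path)) {
    series <- read_assay_csv(assay_path)
    exp_dg <- stats::setNames(
      abs_dg(series$measurements$value_molar, constants),
      series$measurements$compound_id
    )
  }
  perturbation_graph(df, exp_dg = exp_dg)
}

#' @rdname read_graph_csv
#' @param g A [perturbation_graph()] to write.
#' @export
write_graph_csv <- function(g, path) {
  stopifnot(inherits(g, "perturbation_graph"))
  utils::write.csv(as.data.frame(g$edges), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a reproducibility survey from a manifest
#'
#' The manifest is a YAML file listing assay CSVs grouped by target,
#' together with the censoring policy and bootstrap settings:
#'
#' ```yaml
#' assays:
#'   - {path: assay1.csv, target: protA}
#'   - {path: assay2.csv, target: protA}
#' censoring: {policy: qualifier_only, plateau_k: 3}
#' bootstrap: {n_boot: 10000, seed: 42}
#' ```
#'
#' Every unordered pair of assays sharing a target becomes one comparison
#' (compounds measured by more than two assays therefore contribute all
#' assay pairs as separate comparisons), and comparisons are aggregated
#' overall and by category with [survey_aggregate()]. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param manifest Path to the manifest YAML.
#' @param output_dir Optional directory: when given, writes
#'   `survey_summary.json`, `comparisons.tsv`, `removed.tsv` and a
#'   `run_record.json` (config, input digests, package version).
#' @return The [survey_aggregate()] result, plus `removed` (censoring log
#'   over all comparisons, with comparison labels).
#' @export
run_survey <- function(manifest, output_dir = NULL) {
  cfg <- yaml::read_yaml(manifest)
  if (is.null(cfg$assays) || length(cfg$assays) < 2L) {
    stop("manifest must list at least two assays", call. = FALSE)
  }
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  policy <- cfg$censoring$policy %||% "qualifier_only"
  plateau_k <- cfg$censoring$plateau_k %||% 3L
  n_boot <- cfg$bootstrap$n_boot %||% 10000L
  seed <- cfg$bootstrap$seed
  if (is.null(seed)) stop("manifest must set bootstrap: seed", call. = FALSE)

  assays <- lapply(cfg$assays, function(a) {
    list(series = read_assay_csv(resolve(a$path)), target = a$target %||% "target")
  })
  targets <- vapply(assays, function(a) a$target, "")
  comparisons <- list()
  removed <- list()
  for (tg in unique(targets)) {
    idx <- which(targets == tg)
    if (length(idx) < 2L) next
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (j <= i) next
        cmp <- compare_assays(
          assays[[idx[i]]]$series, assays[[idx[j]]]$series,
          policy = policy, plateau_k = plateau_k
        )
        comparisons[[length(comparisons) + 1L]] <- cmp
        if (nrow(cmp$removed) > 0L) {
          removed[[length(removed) + 1L]] <- dplyr::mutate(
            cmp$removed,
            comparison = cmp$metrics$label, target = tg
          )
        }
      }
    }
  }
  if (length(comparisons) == 0L) {
    stop("no target has two or more assays to compare", call. = FALSE)
  }
  res <- survey_aggregate(comparisons, n_boot = n_boot, seed = seed)
  res$removed <- if (length(removed) > 0L) dplyr::bind_rows(removed) else
    tibble::tibble(compound_id = character(), reason = character(),
      comparison = character(), target = character())

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(
        summary = res$summary,
        n_comparisons = length(comparisons)
      ),
      file.path(output_dir, "survey_summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    utils::write.table(res$comparisons, file.path(output_dir, "comparisons.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    utils::write.table(res$removed, file.path(output_dir, "removed.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    digests <- vapply(cfg$assays, function(a) {
      unname(tools::md5sum(resolve(a$path)))
    }, "")
    jsonlite::write_json(
      list(
        config = cfg,
        inputs = stats::setNames(as.list(digests),
          vapply(cfg$assays, function(a) a$path, "")),
        package_version = as.character(utils::packageVersion("fepbench"))
      ),
      file.path(output_dir, "run_record.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  res
}

#' Export a metric report as JSON
#'
#' Writes per-comparison metrics and aggregate summaries (full precision)
#' in a layout mirroring the survey's summary tables.
#'
#' @param survey_result A [run_survey()] / [survey_aggregate()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(survey_result, path) {
  jsonlite::write_json(
    list(
      comparisons = survey_result$comparisons,
      summary = survey_result$summary
    ),
    path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
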