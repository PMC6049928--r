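# End-to-end orchestration: configuration handling, per-stratum analysis
# (bucket -> univariate -> PCA / PLS-DA -> ROC -> records) and the
# cross-strata heat map, with optional archiving of every intermediate.

#' Analyse one control/study stratum of a bucket table
#'
#' Runs the full per-stratum battery: univariate screen, PCA with the
#' scores-plot separation test, PLS-DA with VIP, separation test on the
#' PLS-DA scores, cross-validated Q2, AUROC and merged biomarker records.
#'
#' @param table A `bucket_table` whose metadata carries a `group` column
#'   (values `"control"` / `"study"`).
#' @param alpha Critical alpha (default 0.05).
#' @param fc_threshold Volcano fold-change threshold (default 2).
#' @param n_components PLS-DA latent variables (default 3).
#' @param n_folds Cross-validation folds (default 7).
#' @param seed Seed for the cross-validation partition.
#' @param scaling Column scaling tag (default `"center"`).
#' @param metabolite Optional bucket-to-metabolite mapping.
#' @return List of class `stratum_analysis` with elements `stats`, `pca`,
#'   `pca_separation`, `plsda`, `plsda_separation`, `q2`, `records` and a
#'   `summary` row.
#' @export
analyze_stratum <- function(table, alpha = 0.05, fc_threshold = 2,
                            n_components = 3, n_folds = 7, seed = 1,
                            scaling = "center", metabolite = NULL) {
  stopifnot(inherits(table, "bucket_table"))
  stats <- run_univariate(table, alpha = alpha, fc_threshold = fc_threshold)
  pca <- fit_pca(table, n_components = 2, scaling = scaling)
  pca_sep <- separation_test(pca$scores, table$samples$group, alpha = alpha)
  plsda <- fit_plsda(table, n_components = n_components, scaling = scaling)
  pls_sep <- separation_test(plsda$scores[, 1:2, drop = FALSE],
                             table$samples$group, alpha = alpha)
  cv <- cross_validate_q2(table, n_components = n_components,
                          n_folds = n_folds, seed = seed, scaling = scaling)
  records <- biomarker_records(table, stats, plsda$vip,
                               metabolite = metabolite)
  summary <- data.frame(
    n_buckets = ncol(table$areas),
    n_control = sum(table$samples$group == "control"),
    n_study = sum(table$samples$group == "study"),
    n_sig_uncorrected = sum(stats$sig_uncorrected),
    n_sig_bonferroni = sum(stats$sig_bonferroni),
    n_vip_gt1 = sum(plsda$vip > 1),
    pca_mahalanobis_d = pca_sep$mahalanobis_d,
    pca_f = pca_sep$f_stat, pca_f_crit = pca_sep$f_crit,
    plsda_mahalanobis_d = pls_sep$mahalanobis_d,
    plsda_f = pls_sep$f_stat, plsda_f_crit = pls_sep$f_crit,
    r2y_cum = plsda$r2y_cum[plsda$n_components], q2_cum = cv$q2_cum)
  structure(list(stats = stats, pca = pca, pca_separation = pca_sep,
                 plsda = plsda, plsda_separation = pls_sep, q2 = cv,
                 records = records, summary = summary),
            class = "stratum_analysis")
}

.pipeline_defaults <- function() {
  list(alpha = 0.05, fc_threshold = 2, normalization = "none",
       scaling = "center", n_components = 3, n_folds = 7, seed = 1,
       bucket_half_width = 0.005, render = TRUE, n_per_group = 24)
}

#' Load and validate a pipeline configuration
#'
#' Configurations are plain lists or YAML files.  Two modes exist:
#' simulation (`simulate: true` with `matrix`, `ages`, `sex`,
#' `n_per_group`, optional `planted` fold map) and file mode
#' (`spectra_dir`, `manifest`, `buckets` paths).  Unspecified analysis
#' parameters take the documented defaults.
#'
#' @param config A named list or path to a YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$fc_threshold >= 1,
            cfg$n_components >= 1, cfg$n_folds >= 2)
  if (isTRUE(cfg$simulate)) {
    if (is.null(cfg$matrix)) stop("simulation config needs 'matrix'")
    if (is.null(cfg$ages)) cfg$ages <- "15"
    if (is.null(cfg$sex)) cfg$sex <- "M"
    if (identical(cfg$planted, "default"))
      cfg$planted <- as.list(default_fold_map(cfg$matrix))
  } else {
    for (f in c("spectra_dir", "manifest", "buckets"))
      if (is.null(cfg[[f]]))
        stop("file-mode config needs '", f, "'")
      else if (!file.exists(cfg[[f]]))
        stop("config path does not exist: ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

# build one referenced bucket table for a subset of manifest rows
.table_for_stratum <- function(manifest_rows, spectra_dir, defs,
                               normalization) {
  paths <- file.path(spectra_dir, manifest_rows$file)
  spectra <- lapply(paths, read_spectrum)
  spectra <- lapply(spectra, reference_to_tsp)
  names(spectra) <- manifest_rows$sample_id
  build_bucket_table(spectra, defs, manifest = manifest_rows,
                     normalization = normalization)
}

#' Run the full stratified screening pipeline
#'
#' Executes simulate/load -> TSP referencing -> bucket integration ->
#' univariate screen -> PCA and PLS-DA with separation tests -> Q2 ->
#' AUROC -> combined scores, for every (matrix, age, sex) stratum, and
#' assembles the cross-strata heat map.  With the same configuration and
#' seed the report is identical run to run.
#'
#' @param config A `run_config`, plain list, or YAML path.
#' @param out_dir Optional directory; when given, every intermediate table
#'   (manifest, per-stratum bucket tables, statistics, records, heat map)
#'   is archived there as comma-separated text.
#' @return Object of class `run_report`: per-stratum `stratum_analysis`
#'   objects, the heat map, the configuration echo and a summary table.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tables <- list()   # per stratum: bucket_table + metabolite map
  if (isTRUE(cfg$simulate)) {
    lib <- template_library(cfg$matrix)
    planted <- unlist(cfg$planted %||% list())
    defs <- bucket_definitions(lib, half_width = cfg$bucket_half_width)
    met_map <- stats::setNames(defs$metabolite, defs$bucket_id)
    for (i in seq_along(cfg$ages)) {
      age <- as.character(cfg$ages[[i]])
      sex <- if (length(cfg$sex) > 1) cfg$sex[[i]] else cfg$sex
      design <- cohort_design(
        n_per_group = cfg$n_per_group,
        strata = data.frame(matrix = cfg$matrix, age_months = age, sex = sex),
        planted_effects = planted,
        seed = cfg$seed + i - 1L)
      if (isTRUE(cfg$render)) {
        dir <- file.path(tempdir(), sprintf("ms_run_%s_%s", age,
                                            as.integer(cfg$seed)))
        res <- generate_cohort(design, out_dir = dir)
        tb <- .table_for_stratum(res$manifest, dir, defs, cfg$normalization)
      } else {
        set.seed(design$seed)
        tb <- simulate_bucket_table(lib, n_per_group = cfg$n_per_group,
                                    planted_effects = planted)
      }
      tables[[age]] <- list(table = tb, metabolite = met_map)
    }
  } else {
    manifest <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
    defs <- utils::read.csv(cfg$buckets, stringsAsFactors = FALSE)
    met_map <- if ("metabolite" %in% names(defs))
      stats::setNames(defs$metabolite, defs$bucket_id) else NULL
    strata <- unique(manifest[, c("matrix", "age_months", "sex")])
    for (s in seq_len(nrow(strata))) {
      rows <- merge(manifest, strata[s, ])
      key <- paste(strata[s, ], collapse = "_")
      tables[[key]] <- list(
        table = .table_for_stratum(rows, cfg$spectra_dir, defs,
                                   cfg$normalization),
        metabolite = met_map)
    }
  }
  analyses <- lapply(names(tables), function(key) {
    analyze_stratum(tables[[key]]$table, alpha = cfg$alpha,
                    fc_threshold = cfg$fc_threshold,
                    n_components = cfg$n_components, n_folds = cfg$n_folds,
                    seed = cfg$seed, scaling = cfg$scaling,
                    metabolite = tables[[key]]$metabolite)
  })
  names(analyses) <- names(tables)
  heatmap <- assemble_heatmap(lapply(analyses, `[[`, "records"),
                              alpha = cfg$alpha)
  summary <- do.call(rbind, lapply(names(analyses), function(key)
    cbind(stratum = key, analyses[[key]]$summary)))
  report <- structure(list(strata = analyses, heatmap = heatmap,
                           summary = summary, config = cfg),
                      class = "run_report")
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(heatmap, file.path(out_dir, "heatmap.csv"),
                     row.names = FALSE)
    for (key in names(analyses)) {
      utils::write.csv(analyses[[key]]$stats,
                       file.path(out_dir, paste0("stats_", key, ".csv")),
                       row.names = FALSE)
      utils::write.csv(analyses[[key]]$records,
                       file.path(out_dir, paste0("records_", key, ".csv")),
                       row.names = FALSE)
      tb <- tables[[key]]$table
      utils::write.csv(cbind(sample_id = rownames(tb$areas),
                             as.data.frame(tb$areas)),
                       file.path(out_dir, paste0("buckets_", key, ".csv")),
                       row.names = FALSE)
    }
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", length(x$strata), "stratum/strata\n")
  for (key in names(x$strata)) {
    s <- x$strata[[key]]$summary
    cat(sprintf(paste0("  [%s] %d buckets; %d sig (p<alpha), %d Bonferroni,",
                       " %d VIP>1; PCA D=%.2f F=%.2f/%.2f;",
                       " PLS-DA D=%.2f F=%.2f/%.2f; R2Y=%.2f Q2=%.2f\n"),
                key, s$n_buckets, s$n_sig_uncorrected, s$n_sig_bonferroni,
                s$n_vip_gt1, s$pca_mahalanobis_d, s$pca_f, s$pca_f_crit,
                s$plsda_mahalanobis_d, s$plsda_f, s$plsda_f_crit,
                s$r2y_cum, s$q2_cum))
  }
  cat(sprintf("  heat map: %d cells, %d shaded\n",
              nrow(x$heatmap), sum(x$heatmap$shaded)))
  invisible(x)
}
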