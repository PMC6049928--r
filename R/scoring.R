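# Biomarker evidence scoring: rank-based AUROC, the combined
# -log10(p) + VIP heat-map score, merged per-bucket evidence records,
# ranking and longitudinal heat-map assembly across strata.

#' Rank-based AUROC of one bucket
#'
#' Mann-Whitney U with midrank tie handling divided by the product of the
#' group sizes.  The reported AUC is oriented to be >= 0.5, with a
#' `direction` flag giving the sign of the observed group difference
#' (`"up_in_study"` / `"down_in_study"`); the raw study-over-control
#' probability is returned as `auc_raw`.
#'
#' @param control Control-group values (>= 1).
#' @param study Study-group values (>= 1).
#' @return List with `auc`, `auc_raw`, `direction`, `n_control`, `n_study`.
#' @examples
#' auroc(c(1, 2, 3), c(2, 3, 4))  # 7 of 9 pairs -> 0.778
#' @export
auroc <- function(control, study) {
  if (!length(control) || !length(study)) stop("empty group")
  n1 <- length(control); n2 <- length(study)
  r <- rank(c(control, study))  # midranks
  u_study <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  raw <- u_study / (n1 * n2)
  direction <- if (mean(study) >= mean(control)) "up_in_study" else "down_in_study"
  list(auc = max(raw, 1 - raw), auc_raw = raw, direction = direction,
       n_control = n1, n_study = n2)
}

#' Combined heat-map shading score
#'
#' For a positive fold change (> +1) the score is `-log10(p) + VIP`; for a
#' negative fold change it is `+log10(p) - VIP`.  Cells are shaded when
#' the score reaches the minimum shading value 2.3 in magnitude, the value
#' of `-log10(0.05) + 1.0` at the significance and VIP thresholds; a fold
#' change of exactly +1 (no change) scores 0 and is never shaded.
#'
#' @param p_value Bucket p-value (0 < p <= 1).
#' @param vip VIP score (>= 0).
#' @param fold_change Signed fold change (|fold| >= 1).
#' @param threshold Minimum shading magnitude (default 2.3).
#' @return List with `score` and `shaded`.
#' @examples
#' heatmap_score(0.05, 1.0, 2.0)   # 2.301, shaded (boundary)
#' heatmap_score(0.001, 2.0, -1.5) # -5, shaded
#' @export
heatmap_score <- function(p_value, vip, fold_change, threshold = 2.3) {
  if (!is.numeric(p_value) || p_value <= 0 || p_value > 1)
    stop("p_value must be in (0, 1]")
  stopifnot(vip >= 0, is.finite(fold_change))
  if (fold_change > 1) {
    score <- -log10(p_value) + vip
    shaded <- score >= threshold
  } else if (fold_change < 0) {
    score <- log10(p_value) - vip
    shaded <- score <= -threshold
  } else {
    score <- 0
    shaded <- FALSE
  }
  list(score = score, shaded = shaded)
}

#' Merge per-bucket evidence into biomarker records
#'
#' Joins the univariate screen, VIP scores and AUROC results of one
#' stratum into a single table and attaches the combined heat-map score.
#'
#' @param table The `bucket_table` the statistics were computed from.
#' @param stats Output of [run_univariate].
#' @param vip Named VIP vector (e.g. `model$vip`).
#' @param control_ids,study_ids Group sample ids; defaults to the table's
#'   `group` metadata.
#' @param metabolite Optional named character vector mapping bucket ids to
#'   metabolite names (e.g. from [bucket_definitions] or ground truth).
#' @return Data frame with one row per bucket: p-value, fold change, VIP,
#'   AUC, volcano class and heat-map score.
#' @export
biomarker_records <- function(table, stats, vip,
                              control_ids = NULL, study_ids = NULL,
                              metabolite = NULL) {
  stopifnot(inherits(table, "bucket_table"))
  if (is.null(control_ids)) {
    control_ids <- table$samples$sample_id[table$samples$group == "control"]
    study_ids <- table$samples$sample_id[table$samples$group == "study"]
  }
  rec <- stats[, c("bucket_id", "p_value", "t_stat", "fold_change",
                   "fold_error", "sig_uncorrected", "sig_bonferroni",
                   "volcano_class")]
  rec$vip <- unname(vip[rec$bucket_id])
  roc <- lapply(rec$bucket_id, function(b)
    auroc(table$areas[control_ids, b], table$areas[study_ids, b]))
  rec$auc <- vapply(roc, `[[`, numeric(1), "auc")
  rec$direction <- vapply(roc, `[[`, character(1), "direction")
  hs <- Map(heatmap_score, rec$p_value, rec$vip, rec$fold_change)
  rec$heatmap_score <- vapply(hs, `[[`, numeric(1), "score")
  rec$shaded <- vapply(hs, `[[`, logical(1), "shaded")
  if (!is.null(metabolite))
    rec$metabolite <- unname(metabolite[rec$bucket_id])
  rownames(rec) <- NULL
  rec
}

#' Rank biomarker records by combined evidence
#'
#' Descending by the magnitude of the combined heat-map score, ties broken
#' by AUC, then by log2 fold-change magnitude, then bucket id (stable).
#'
#' @param records Output of [biomarker_records].
#' @return The records reordered, with a `rank` column prepended.
#' @export
rank_biomarkers <- function(records) {
  o <- order(-abs(records$heatmap_score), -records$auc,
             -abs(log2(abs(records$fold_change))), records$bucket_id)
  out <- records[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Assemble a longitudinal heat map across strata
#'
#' Rows are metabolites (or buckets) that pass the inclusion rule -
#' significant by p-value or by VIP > 1 in at least one stratum - and
#' columns are strata ordered by age ascending with tumor groups last.
#' When several buckets map to one metabolite the bucket with the largest
#' score magnitude represents it.  `shade_fraction` is each |score|
#' normalised to the map-wide maximum.
#'
#' @param records_by_stratum Named list of [biomarker_records] outputs;
#'   names label the strata (e.g. `"5"`, `"11"`, `"15"`, `"tumor"`).
#' @param alpha Significance threshold for the inclusion rule.
#' @param vip_threshold VIP threshold for the inclusion rule.
#' @param collapse How to collapse multiple buckets of one metabolite:
#'   `"max_score"` (default) or `"none"` (keep buckets as rows).
#' @return Long-format data frame (`metabolite`, `stratum`, `score`,
#'   `shaded`, `shade_fraction`, `direction`) of class `heatmap_table`;
#'   empty (with a warning) if nothing passes the rule.
#' @export
assemble_heatmap <- function(records_by_stratum, alpha = 0.05,
                             vip_threshold = 1,
                             collapse = c("max_score", "none")) {
  collapse <- match.arg(collapse)
  stopifnot(length(records_by_stratum) >= 1)
  strata <- names(records_by_stratum)
  if (is.null(strata)) strata <- as.character(seq_along(records_by_stratum))
  long <- do.call(rbind, lapply(seq_along(records_by_stratum), function(i) {
    r <- records_by_stratum[[i]]
    key <- if (!is.null(r$metabolite))
      ifelse(is.na(r$metabolite) | !nzchar(r$metabolite),
             r$bucket_id, r$metabolite) else r$bucket_id
    data.frame(metabolite = key, bucket_id = r$bucket_id,
               stratum = strata[i], p_value = r$p_value, vip = r$vip,
               score = r$heatmap_score, shaded = r$shaded,
               fold_change = r$fold_change, stringsAsFactors = FALSE)
  }))
  pass <- long$p_value < alpha | long$vip > vip_threshold
  keep_keys <- unique(long$metabolite[pass])
  if (!length(keep_keys)) {
    warning("no metabolite passes the inclusion rule; empty heat map")
    return(structure(data.frame(metabolite = character(),
                                stratum = character(), score = numeric(),
                                shaded = logical(),
                                shade_fraction = numeric(),
                                direction = character()),
                     class = c("heatmap_table", "data.frame")))
  }
  long <- long[long$metabolite %in% keep_keys, , drop = FALSE]
  if (collapse == "max_score") {
    split_key <- interaction(long$metabolite, long$stratum, drop = TRUE)
    best <- lapply(split(long, split_key), function(g)
      g[which.max(abs(g$score)), , drop = FALSE])
    long <- do.call(rbind, best)
  }
  # stratum order: numeric ages ascending, then tumor, then others
  ages <- suppressWarnings(as.numeric(strata))
  ord <- order(is.na(ages), ages, strata)
  long$stratum <- factor(long$stratum, levels = strata[ord])
  max_abs <- max(abs(long$score))
  long$shade_fraction <- if (max_abs > 0) abs(long$score) / max_abs else 0
  long$direction <- ifelse(long$score > 0, "up_in_study",
                           ifelse(long$score < 0, "down_in_study", "none"))
  long <- long[order(long$metabolite, long$stratum),
               c("metabolite", "stratum", "score", "shaded",
                 "shade_fraction", "direction")]
  rownames(long) <- NULL
  structure(long, class = c("heatmap_table", "data.frame"))
}
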