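# Per-bucket two-group screening: Welch's t-test, Bonferroni-corrected
# significance, signed fold changes with delta-method errors, and volcano
# classification.

#' Welch's two-sample t-test
#'
#' The statistic is oriented study minus control:
#' `t = (mean(y) - mean(x)) / sqrt(sx^2/nx + sy^2/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.  The
#' formulas are written out explicitly so that degenerate buckets (both
#' groups constant) are handled deterministically rather than failing:
#' equal constants give p = 1, different constants give p = 0, each with a
#' warning.
#'
#' @param x Control-group values (length >= 2).
#' @param y Study-group values (length >= 2).
#' @return List with `t_stat`, `df`, `p_value`.
#' @examples
#' welch_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      warning("both groups constant and equal; p = 1")
      return(list(t_stat = 0, df = NA_real_, p_value = 1))
    }
    warning("both groups constant but different; p = 0")
    return(list(t_stat = sign(mean(y) - mean(x)) * Inf, df = NA_real_,
                p_value = 0))
  }
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Bonferroni-corrected critical alpha
#'
#' The uncorrected critical alpha divided by the number of buckets tested.
#'
#' @param alpha Uncorrected critical alpha (0 < alpha < 1).
#' @param n_tests Number of buckets in the table (>= 1).
#' @return Corrected alpha.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.numeric(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Signed study/control fold change with delta-method error
#'
#' The ratio of group means `r = mean(y)/mean(x)` reported as `r` when
#' `r >= 1` and as `-1/r` otherwise, so that magnitude is always >= 1 and
#' the sign encodes direction (negative = lower in the study group).  The
#' error is first-order propagation of the ratio of means:
#' `|fold| * sqrt((sx/mean(x))^2/nx + (sy/mean(y))^2/ny)`.
#'
#' @param x Control-group values (mean > 0).
#' @param y Study-group values (mean > 0).
#' @return List with `fold_change` and `fold_error`.
#' @export
signed_fold_change <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  if (mx <= 0) stop("control group mean is non-positive")
  if (my <= 0) stop("study group mean is non-positive")
  r <- my / mx
  fold <- if (r >= 1) r else -1 / r
  rel <- sqrt((stats::sd(x) / mx)^2 / length(x) +
              (stats::sd(y) / my)^2 / length(y))
  list(fold_change = fold, fold_error = abs(fold) * rel)
}

#' Volcano-plot classification of one bucket
#'
#' `"green"`: significant (p < alpha) with more than a two-fold change
#' (`|log2(|fold|)| > 1` at the default threshold); `"red"`: significant
#' below the fold threshold; `"grey"`: not significant.
#'
#' @param p_value Welch p-value.
#' @param fold_change Signed fold change.
#' @param alpha Significance threshold (default 0.05).
#' @param fc_threshold Fold-change threshold (default 2).
#' @return One of `"green"`, `"red"`, `"grey"`.
#' @export
volcano_classify <- function(p_value, fold_change, alpha = 0.05,
                             fc_threshold = 2) {
  stopifnot(is.finite(p_value), is.finite(fold_change))
  if (p_value >= alpha) return("grey")
  if (abs(log2(abs(fold_change))) > log2(fc_threshold)) "green" else "red"
}

#' Per-bucket univariate screening of a bucket table
#'
#' Runs [welch_test] and [signed_fold_change] on every bucket for a
#' control/study comparison, flags significance at the uncorrected alpha
#' and at the Bonferroni-corrected alpha (alpha divided by the number of
#' buckets), attaches the volcano class, and sorts by p-value.
#'
#' @param table A `bucket_table`.
#' @param control_ids,study_ids Sample ids of the two groups.  Defaults to
#'   the `group` column of the table metadata when present.
#' @param alpha Uncorrected critical alpha (default 0.05).
#' @param fc_threshold Volcano fold-change threshold (default 2).
#' @return Data frame with one row per bucket: `bucket_id`, `p_value`,
#'   `t_stat`, `df`, `fold_change`, `fold_error`, `sig_uncorrected`,
#'   `sig_bonferroni`, `volcano_class`, sorted by p ascending.  The
#'   corrected alpha is in attribute `"bonferroni_alpha"`.
#' @export
run_univariate <- function(table, control_ids = NULL, study_ids = NULL,
                           alpha = 0.05, fc_threshold = 2) {
  stopifnot(inherits(table, "bucket_table"))
  if (is.null(control_ids) || is.null(study_ids)) {
    if (!"group" %in% names(table$samples))
      stop("no group metadata; supply control_ids and study_ids")
    control_ids <- table$samples$sample_id[table$samples$group == "control"]
    study_ids <- table$samples$sample_id[table$samples$group == "study"]
  }
  ids <- rownames(table$areas)
  missing <- setdiff(c(control_ids, study_ids), ids)
  if (length(missing))
    stop("sample id not in bucket table: ", paste(missing, collapse = ", "))
  if (length(intersect(control_ids, study_ids)))
    stop("control and study groups overlap")
  stopifnot(length(control_ids) >= 2, length(study_ids) >= 2)
  n_tests <- ncol(table$areas)
  alpha_bonf <- bonferroni_alpha(alpha, n_tests)
  rows <- lapply(seq_len(n_tests), function(j) {
    x <- table$areas[control_ids, j]
    y <- table$areas[study_ids, j]
    wt <- welch_test(x, y)
    fc <- signed_fold_change(x, y)
    data.frame(bucket_id = colnames(table$areas)[j],
               p_value = wt$p_value, t_stat = wt$t_stat, df = wt$df,
               fold_change = fc$fold_change, fold_error = fc$fold_error,
               sig_uncorrected = wt$p_value < alpha,
               sig_bonferroni = wt$p_value < alpha_bonf,
               volcano_class = volcano_classify(wt$p_value, fc$fold_change,
                                                alpha, fc_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$bucket_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bonferroni_alpha") <- alpha_bonf
  attr(out, "n_tests") <- n_tests
  out
}
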