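# Multivariate modelling: PCA, the Mahalanobis-distance F-test for group
# separation in a scores plot, NIPALS PLS-DA with VIP scores and
# cross-validated R2Y / Q2.

.scale_matrix <- function(X, scaling = c("center", "unit_variance", "pareto")) {
  scaling <- match.arg(scaling)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- rep(1, ncol(X))
  if (scaling != "center") {
    sdv <- apply(X, 2, stats::sd)
    if (any(sdv == 0))
      stop("constant bucket under ", scaling, " scaling: ",
           paste(colnames(X)[sdv == 0], collapse = ", "))
    s <- if (scaling == "unit_variance") sdv else sqrt(sdv)
    Xc <- sweep(Xc, 2, s, "/")
  }
  list(X = Xc, center = mu, scale = s, scaling = scaling)
}

# fixed sign convention: each loading column's largest-|.| element positive
.fix_signs <- function(loadings, ...) {
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  extras <- list(...)
  out <- c(list(loadings = sweep(loadings, 2, flip, "*")),
           lapply(extras, function(m) sweep(m, 2, flip, "*")))
  out$flip <- flip
  out
}

#' Principal component analysis of a bucket table
#'
#' Deterministic SVD-based PCA after the chosen column scaling.  Loadings
#' follow a fixed sign convention (largest-magnitude element of each
#' column positive) so repeated fits are identical.
#'
#' @param table A `bucket_table`, or a plain numeric matrix.
#' @param n_components Number of components (<= min(samples - 1, buckets)).
#' @param scaling `"center"` (default; bucket areas share units),
#'   `"unit_variance"` or `"pareto"`.
#' @return Object of class `pca_model` with `scores`, `loadings`,
#'   `center`, `scale`, `explained_variance_fraction`.
#' @export
fit_pca <- function(table, n_components = 2,
                    scaling = c("center", "unit_variance", "pareto")) {
  X <- if (inherits(table, "bucket_table")) table$areas else as.matrix(table)
  scaling <- match.arg(scaling)
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds min(samples - 1, buckets)")
  sc <- .scale_matrix(X, scaling)
  sv <- svd(sc$X)
  total_var <- sum(sv$d^2)
  keep <- seq_len(n_components)
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- sc$X %*% loadings
  fx <- .fix_signs(loadings, scores = scores)
  dimnames(fx$loadings) <- list(colnames(X), paste0("PC", keep))
  dimnames(fx$scores) <- list(rownames(X), paste0("PC", keep))
  structure(list(scores = fx$scores, loadings = fx$loadings,
                 center = sc$center, scale = sc$scale, scaling = scaling,
                 explained_variance_fraction = sv$d[keep]^2 / total_var),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; explained fractions: %s\n",
              ncol(x$scores),
              paste(sprintf("%.3f", x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Mahalanobis-distance F-test for scores-plot group separation
#'
#' Two-sample Hotelling T-squared on the score coordinates: the squared
#' Mahalanobis distance between group centroids under the pooled
#' within-group covariance, converted to Hotelling's T2 and to an exact F
#' statistic with `df1 = p` (number of score dimensions) and
#' `df2 = n1 + n2 - p - 1`.  Separation is significant when the F
#' statistic exceeds the upper-alpha F quantile.
#'
#' @param scores Numeric matrix of score coordinates (samples x p,
#'   default usage p = 2).
#' @param groups Two-level factor/character vector of group labels.
#' @param alpha Test level (default 0.05).
#' @return Object of class `separation_test` with `mahalanobis_d`, `t2`,
#'   `f_stat`, `f_crit`, `df1`, `df2`, `p_value`, `significant`.
#' @export
separation_test <- function(scores, groups, alpha = 0.05) {
  scores <- as.matrix(scores)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("exactly two group levels required")
  groups <- droplevels(groups)
  g1 <- scores[groups == levels(groups)[1], , drop = FALSE]
  g2 <- scores[groups == levels(groups)[2], , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2); p <- ncol(scores)
  stopifnot(n1 >= 3, n2 >= 3)
  delta <- colMeans(g2) - colMeans(g1)
  S <- ((n1 - 1) * stats::cov(g1) + (n2 - 1) * stats::cov(g2)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; use fewer score dimensions"))
  d2 <- drop(t(delta) %*% Sinv %*% delta)
  t2 <- (n1 * n2 / (n1 + n2)) * d2
  df1 <- p; df2 <- n1 + n2 - p - 1
  f_stat <- df2 / (p * (n1 + n2 - 2)) * t2
  f_crit <- stats::qf(1 - alpha, df1, df2)
  structure(list(mahalanobis_d = sqrt(d2), t2 = t2, f_stat = f_stat,
                 f_crit = f_crit, df1 = df1, df2 = df2, alpha = alpha,
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 significant = f_stat > f_crit),
            class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  cat(sprintf(paste0("<separation_test> Mahalanobis distance = %.3g, ",
                     "F-statistic = %.3g, F-critical = %.3g (df %d, %d): %s\n"),
              x$mahalanobis_d, x$f_stat, x$f_crit, x$df1, x$df2,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' PLS-DA by NIPALS
#'
#' Partial least squares regression of a centered 0/1 group indicator on
#' the scaled bucket matrix, one latent variable at a time with deflation
#' of X.  With a single response the NIPALS weight vector is
#' `w = X'y / ||X'y||` exactly, so the fit is deterministic.  Cumulative
#' R2Y is `1 - RSS/TSS` of the indicator.
#'
#' @param table A `bucket_table` or numeric matrix.
#' @param groups Two-level group labels, or `NULL` to use the table's
#'   `group` metadata column.
#' @param n_components Number of latent variables (default 3).
#' @param scaling Column scaling passed to the same convention as
#'   [fit_pca].
#' @return Object of class `plsda_model` with `weights`, `loadings`,
#'   `y_loadings`, `scores`, `r2y`, `r2y_cum`, `vip`, plus the scaling
#'   bookkeeping needed for prediction.
#' @export
fit_plsda <- function(table, groups = NULL, n_components = 3,
                      scaling = c("center", "unit_variance", "pareto")) {
  X <- if (inherits(table, "bucket_table")) table$areas else as.matrix(table)
  if (is.null(groups)) {
    if (!inherits(table, "bucket_table") ||
        !"group" %in% names(table$samples))
      stop("groups not supplied and no group metadata present")
    groups <- table$samples$group
  }
  scaling <- match.arg(scaling)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two group levels required")
  if (min(table(groups)) < 3) stop("both groups need at least 3 samples")
  y01 <- as.numeric(groups == levels(groups)[2])
  if (stats::var(y01) == 0) stop("group indicator has zero variance")
  sc <- .scale_matrix(X, scaling)
  Xd <- sc$X
  y_mean <- mean(y01)
  yd <- y01 - y_mean
  n <- nrow(Xd); k <- ncol(Xd); A <- n_components
  W <- matrix(0, k, A); P <- matrix(0, k, A); Tm <- matrix(0, n, A)
  q <- numeric(A); ssy <- numeric(A)
  tss <- sum(yd^2)
  y_res <- yd
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, y_res))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # X exhausted; keep remaining components at zero
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]; ssy <- ssy[seq_len(a - 1)]
      A <- a - 1L
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    p_a <- drop(crossprod(Xd, t)) / tt
    q_a <- sum(y_res * t) / tt
    Xd <- Xd - tcrossprod(t, p_a)
    y_res <- y_res - q_a * t
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t
    q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  if (A == 0) stop("no usable latent variable (X has no variance)")
  r2y <- ssy / tss
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("LV", seq_len(A)))
  dimnames(Tm) <- list(rownames(X), paste0("LV", seq_len(A)))
  model <- structure(
    list(weights = W, loadings = P, y_loadings = q, scores = Tm,
         r2y = r2y, r2y_cum = cumsum(r2y), ssy = ssy,
         n_components = A, groups = groups, levels = levels(groups),
         center = sc$center, scale = sc$scale, scaling = scaling,
         y_mean = y_mean),
    class = "plsda_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components; R2Y(cum) = %.3f\n",
              x$n_components, x$r2y_cum[x$n_components]))
  invisible(x)
}

#' Predict the group indicator for new samples
#'
#' @param object A `plsda_model`.
#' @param newdata Numeric matrix with the same buckets as the training
#'   table.
#' @param n_components Number of latent variables to use (defaults to all).
#' @param ... Unused.
#' @return Numeric predictions of the 0/1 indicator of the second group
#'   level.
#' @export
predict.plsda_model <- function(object, newdata, n_components = NULL, ...) {
  A <- if (is.null(n_components)) object$n_components else n_components
  stopifnot(A >= 1, A <= object$n_components)
  X <- sweep(as.matrix(newdata), 2, object$center)
  X <- sweep(X, 2, object$scale, "/")
  W <- object$weights[, seq_len(A), drop = FALSE]
  P <- object$loadings[, seq_len(A), drop = FALSE]
  q <- object$y_loadings[seq_len(A)]
  B <- W %*% solve(crossprod(P, W), q)
  drop(X %*% B) + object$y_mean
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(k * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with unit-norm
#' weight columns, `k` buckets and `SSY_a` the y-variance explained by
#' latent variable `a`.  Mean squared VIP equals 1 by construction.
#'
#' @param model A fitted `plsda_model`.
#' @return Named numeric vector of per-bucket VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$weights
  k <- nrow(W)
  w2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip <- sqrt(k * drop(w2 %*% model$ssy) / sum(model$ssy))
  stats::setNames(vip, rownames(W))
}

# stratified fold assignment; re-draws until every fold holds both classes
.stratified_folds <- function(groups, n_folds, max_attempts = 100) {
  for (attempt in seq_len(max_attempts)) {
    folds <- integer(length(groups))
    for (lev in levels(groups)) {
      idx <- sample(which(groups == lev))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      nlevels(droplevels(groups[folds != f])) == 2, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build stratified folds with both classes in every ",
       "training split")
}

#' Cross-validated Q2 of a PLS-DA model
#'
#' Seeded stratified k-fold cross-validation.  For each fold a PLS-DA
#' model is refit on the remaining samples and the held-out group
#' indicators are predicted; `Q2(A) = 1 - PRESS_A / TSS` cumulatively over
#' the first `A` latent variables.
#'
#' @param table A `bucket_table` or numeric matrix.
#' @param groups Two-level labels (`NULL`: table metadata).
#' @param n_components Latent variables (default 3).
#' @param n_folds Folds (default 7), at most twice the smaller group.
#' @param seed Integer seed for the fold partition.
#' @param scaling Column scaling tag.
#' @return List with `q2` (per cumulative component count) and `q2_cum`
#'   (its last element), plus the fold assignment.
#' @export
cross_validate_q2 <- function(table, groups = NULL, n_components = 3,
                              n_folds = 7, seed = 1,
                              scaling = c("center", "unit_variance", "pareto")) {
  X <- if (inherits(table, "bucket_table")) table$areas else as.matrix(table)
  if (is.null(groups)) groups <- table$samples$group
  scaling <- match.arg(scaling)
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2)
  if (n_folds > 2 * min(table(groups)))
    stop("n_folds exceeds twice the smaller group size")
  set.seed(seed)
  folds <- .stratified_folds(groups, n_folds)
  y01 <- as.numeric(groups == levels(groups)[2])
  press <- numeric(n_components)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- fit_plsda(X[tr, , drop = FALSE], groups[tr],
                     n_components = n_components, scaling = scaling)
    # map held-out indicator onto the training model's level coding
    y_te <- as.numeric(as.character(groups[!tr]) == fit$levels[2])
    for (a in seq_len(n_components)) {
      a_use <- min(a, fit$n_components)
      pred <- predict(fit, X[!tr, , drop = FALSE], n_components = a_use)
      press[a] <- press[a] + sum((y_te - pred)^2)
    }
  }
  tss <- sum((y01 - mean(y01))^2)
  q2 <- 1 - press / tss
  list(q2 = q2, q2_cum = q2[n_components], n_folds = n_folds,
       seed = seed, folds = folds)
}
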