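test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(2)
  X <- matrix(rnorm(4 * 3), 4, 3)
  m <- fit_pca(X, n_components = 2)
  ev <- eigen(stats::cov(X))
  # eigenvector comparison up to sign
  for (j in 1:2) {
    v <- ev$vectors[, j]
    expect_lt(min(sum((m$loadings[, j] - v)^2),
                  sum((m$loadings[, j] + v)^2)), 1e-16)
  }
  # scores are centred data projected on the loadings
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(unname(m$scores), unname(Xc %*% m$loadings), tolerance = 1e-12)
  # loadings orthonormal
  expect_equal(crossprod(m$loadings), diag(2), ignore_attr = TRUE,
               tolerance = 1e-8)
  # explained fractions match eigenvalues
  expect_equal(m$explained_variance_fraction,
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
})

test_that("PCA handles rank-1 data and conserves variance", {
  t <- 1:6
  X <- cbind(2 * t, -t, 0.5 * t) + 3
  m <- fit_pca(X, n_components = 2)
  expect_equal(m$explained_variance_fraction[1], 1, tolerance = 1e-9)

  set.seed(3)
  Y <- matrix(rnorm(8 * 5), 8, 5)
  full <- fit_pca(Y, n_components = 5)
  expect_equal(sum(apply(full$scores, 2, stats::var)),
               sum(apply(sweep(Y, 2, colMeans(Y)), 2, stats::var)),
               tolerance = 1e-10)
  # reconstruction at full rank
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_lt(norm(Yc - full$scores %*% t(full$loadings), "F"), 1e-10)

  # constant bucket under unit-variance scaling is refused by name
  Z <- cbind(Y, const = 1)
  expect_error(fit_pca(Z, 2, scaling = "unit_variance"), "const")
})

test_that("the separation F-test reproduces the hand-computed example", {
  g1 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  g2 <- g1 + cbind(rep(3, 4), 0)
  st <- separation_test(rbind(g1, g2), rep(c("control", "study"), each = 4))
  expect_equal(st$mahalanobis_d, sqrt(27), tolerance = 1e-12)
  expect_equal(st$t2, 54, tolerance = 1e-12)
  expect_equal(st$f_stat, 22.5, tolerance = 1e-12)
  expect_equal(st$df1, 2)
  expect_equal(st$df2, 5)
  expect_equal(st$f_crit, stats::qf(0.95, 2, 5), tolerance = 1e-12)
  expect_true(st$significant)
})

test_that("identical centroids give zero distance and no significance", {
  set.seed(4)
  base <- matrix(rnorm(12), 6, 2)
  st <- separation_test(rbind(base, base), rep(c("a", "b"), each = 6))
  expect_equal(st$mahalanobis_d, 0, tolerance = 1e-12)
  expect_equal(st$f_stat, 0, tolerance = 1e-12)
  expect_false(st$significant)
})

test_that("Mahalanobis distance is invariant under invertible linear maps", {
  set.seed(6)
  X <- matrix(rnorm(40), 20, 2)
  X[11:20, 1] <- X[11:20, 1] + 1
  gr <- rep(c("a", "b"), each = 10)
  d0 <- separation_test(X, gr)$mahalanobis_d
  A <- matrix(c(2, 0.5, -1, 3), 2, 2)
  d1 <- separation_test(X %*% A, gr)$mahalanobis_d
  expect_lt(abs(d0 - d1), 1e-8)
})

test_that("the separation test equals Hotelling's T2 from an independent route", {
  set.seed(8)
  for (i in 1:100) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    X <- matrix(rnorm((n1 + n2) * 2), ncol = 2)
    gr <- rep(c("a", "b"), c(n1, n2))
    st <- separation_test(X, gr)
    # oracle: Hotelling-Lawley trace from manova(), T2 = HL * (N - 2)
    hl <- summary(stats::manova(X ~ gr),
                  test = "Hotelling-Lawley")$stats[1, 2]
    expect_equal(st$t2, hl * (n1 + n2 - 2), tolerance = 1e-10)
  }
})

test_that("PLS-DA basics: determinism, orthogonality, R2Y nesting, VIP identity", {
  set.seed(9)
  X <- matrix(rlnorm(20 * 8), 20, 8)
  gr <- rep(c("control", "study"), each = 10)
  X[gr == "study", 1] <- X[gr == "study", 1] * 3
  m1 <- fit_plsda(X, gr, n_components = 3)
  m2 <- fit_plsda(X, gr, n_components = 3)
  expect_identical(m1$scores, m2$scores)  # deterministic NIPALS

  # successive score vectors mutually orthogonal
  G <- crossprod(m1$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))

  # R2Y non-decreasing in components and bounded by the larger model
  expect_true(all(diff(m1$r2y_cum) >= -1e-12))
  m_full <- fit_plsda(X, gr, n_components = 10)
  expect_gte(m_full$r2y_cum[m_full$n_components] + 1e-12, m1$r2y_cum[1])

  # mean squared VIP equals 1; single-predictor VIP is exactly 1
  expect_equal(mean(m1$vip^2), 1, tolerance = 1e-6)
  single <- fit_plsda(X[, 1, drop = FALSE], gr, n_components = 1)
  expect_equal(unname(single$vip), 1, tolerance = 1e-12)

  # VIP against a brute-force evaluation of the formula
  W <- m1$weights; ssy <- m1$ssy; k <- nrow(W)
  vip_brute <- sqrt(k * rowSums(sweep(W^2, 2, ssy / colSums(W^2), "*")) /
                    sum(ssy))
  expect_equal(unname(m1$vip), unname(vip_brute), tolerance = 1e-10)
})

test_that("the informative bucket attains the maximum VIP", {
  wins <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 24
    gr <- rep(c("control", "study"), each = n / 2)
    X <- matrix(rlnorm(n * 10, sdlog = 0.3), n, 10)
    X[gr == "study", 4] <- X[gr == "study", 4] * 4  # only bucket 4 informative
    m <- fit_plsda(X, gr, n_components = 2)
    if (which.max(m$vip) == 4) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("cross-validated Q2 is high for separable data, negative under permutation", {
  set.seed(12)
  n <- 28
  gr <- rep(c("control", "study"), each = n / 2)
  X <- matrix(rnorm(n * 6, sd = 0.1), n, 6)
  X[gr == "study", 1] <- X[gr == "study", 1] + 5  # noiseless separation
  cv <- cross_validate_q2(X, gr, n_components = 2, n_folds = 7, seed = 1)
  expect_gte(cv$q2_cum, 0.9)

  # permuted labels: Q2 <= 0 in expectation
  set.seed(13)
  Xn <- matrix(rlnorm(n * 20, sdlog = 0.4), n, 20)
  q2s <- vapply(1:50, function(s) {
    set.seed(2000 + s)
    cross_validate_q2(Xn, sample(gr), n_components = 3, n_folds = 7,
                      seed = s)$q2_cum
  }, numeric(1))
  expect_lt(mean(q2s), 0)

  # Q2 never meaningfully exceeds R2Y on seeded fixtures
  for (s in 1:5) {
    tb <- simulate_bucket_table(
      with_uniform_cv(template_library("urine"), cv_for_sdlog(0.4)),
      n_per_group = 12,
      planted_effects = c(`3-indoxylsulfate` = -1.8), seed = 300 + s)
    m <- fit_plsda(tb, n_components = 3)
    cv <- cross_validate_q2(tb, n_components = 3, n_folds = 6, seed = s)
    expect_lte(cv$q2_cum, m$r2y_cum[m$n_components] + 0.05)
  }
})

test_that("PCA scores of null cohorts reject at close to the nominal rate", {
  lib <- null_template_library(50, cv = 0.3)
  rej <- vapply(1:200, function(s) {
    tb <- simulate_bucket_table(lib, n_per_group = 24, seed = s)
    p <- fit_pca(tb, 2)
    separation_test(p$scores, tb$samples$group)$significant
  }, logical(1))
  rate <- mean(rej)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("group-size and degeneracy guards fire", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(separation_test(X, c("a", "a", "a", "b", "b")), "at least|>= 3|n2")
  expect_error(fit_plsda(X, rep("a", 5)), "two group levels")
  expect_error(fit_pca(matrix(rnorm(6), 3, 2), n_components = 5),
               "n_components")
  expect_error(cross_validate_q2(X, c("a", "a", "a", "b", "b"), n_folds = 7),
               "n_folds")
})
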