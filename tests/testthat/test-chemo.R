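test_that("preprocessing scales columns as advertised", {
  sim <- simulate_batch_set(seed = 6)
  X <- preprocess(sim$table, "autoscale")
  expect_equal(unname(colMeans(X)), rep(0, ncol(X)), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, stats::sd)), rep(1, ncol(X)),
               tolerance = 1e-12)
  Xc <- preprocess(sim$table, "center")
  expect_equal(apply(Xc, 2, stats::var), apply(sim$table$areas, 2, stats::var))
  # stored parameters reproduce the scaled matrix
  expect_equal(apply_preprocess(sim$table$areas, X), unclass(X)[, ],
               ignore_attr = TRUE)
  bad <- sim$table$areas
  bad[, "5"] <- 1
  expect_error(preprocess(bad, "autoscale"), "5")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  set.seed(11)
  for (trial in 1:5) {
    n <- sample(5:12, 1)
    p <- sample(3:12, 1)
    X <- scale(matrix(stats::rnorm(n * p), n, p), scale = FALSE)
    k <- min(n - 1L, p)
    m <- pca_fit(X, n_components = k)
    oracle <- pca_eigen_oracle(X)
    lam <- oracle$values[seq_len(k)]
    # explained fractions equal the eigenvalue fractions
    expect_equal(m$explained, lam / sum(oracle$values), tolerance = 1e-8)
    # score variances equal the eigenvalues
    expect_equal(unname(apply(m$scores, 2, stats::var)), lam,
                 tolerance = 1e-8)
    # loadings span the same axes (up to sign)
    for (a in seq_len(min(3, k))) {
      expect_equal(abs(sum(m$loadings[, a] * oracle$vectors[, a])), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("PCA handles rank deficiency and orthogonality", {
  u <- 1:6
  v <- c(2, 1, 4, 3)
  X1 <- outer(u - mean(u), v)          # rank 1
  m <- pca_fit(X1, 1)
  expect_equal(m$explained, 1)
  expect_error(pca_fit(X1, 2), "rank")
  sim <- simulate_batch_set(seed = 8)
  m2 <- pca_fit(preprocess(sim$table), 4)
  expect_equal(crossprod(m2$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  st <- crossprod(m2$scores)
  expect_equal(st[upper.tri(st)], rep(0, 6), tolerance = 1e-8)
})

test_that("OPLS-DA without orthogonal components is exactly PLS1", {
  skip_if_not_installed("mixOmics")
  sim <- simulate_batch_set(seed = 3)
  X <- preprocess(sim$table)
  m <- oplsda(X, sim$table$regions, n_orthogonal = 0)
  yc <- m$y_coded - mean(m$y_coded)
  fit <- mixOmics::pls(X, matrix(yc, ncol = 1), ncomp = 1,
                       mode = "regression", scale = FALSE)
  oracle_pred <- predict(fit, X)$predict[, , 1]
  expect_equal(unname(m$scores[, "predictive"] * m$c),
               unname(oracle_pred), tolerance = 1e-10)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  sim <- simulate_batch_set(seed = 9)
  X <- preprocess(sim$table)
  for (k in 1:3) {
    m <- oplsda(X, sim$table$regions, n_orthogonal = k)
    dots <- abs(crossprod(m$scores[, "predictive"], m$scores_orth))
    expect_true(all(dots < 1e-8))
  }
})

test_that("region-contrast data give strong, predictive models", {
  r2y <- q2 <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_batch_set(seed = s)
    m <- oplsda(preprocess(sim$table), sim$table$regions)
    r2y[s] <- m$R2Y
    q2[s] <- m$Q2
  }
  expect_true(all(r2y > 0.8))
  expect_true(all(q2 > 0.4))
})

test_that("VIP satisfies its mean-square identity", {
  for (s in c(2, 13)) {
    sim <- simulate_batch_set(seed = s)
    m <- oplsda(preprocess(sim$table), sim$table$regions)
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-9)
  }
  # a lone informative variable dominates the projection
  set.seed(5)
  y <- rep(c("a", "b"), each = 8)
  X <- matrix(stats::rnorm(16 * 10), 16, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  X[, 1] <- ifelse(y == "a", 2, -2) + stats::rnorm(16, sd = 0.3)
  m <- oplsda(scale(X), y, n_orthogonal = 0)
  v <- vip(m)
  expect_identical(names(which.max(v)), "v1")
  expect_gt(max(v), 1)
})

test_that("S-plot covariance and correlation behave canonically", {
  sim <- simulate_batch_set(seed = 7)
  X <- preprocess(sim$table)
  m <- oplsda(X, sim$table$regions)
  sp <- s_plot(m, X)
  expect_true(all(sign(sp$covariance) == sign(sp$correlation)))
  expect_true(all(abs(sp$correlation) <= 1 + 1e-12))
  # a column equal to the scores has correlation 1
  X2 <- cbind(X, t_copy = m$scores[, "predictive"])
  sp2 <- s_plot(m, X2)
  expect_equal(sp2$correlation[sp2$peak_id == "t_copy"], 1,
               tolerance = 1e-12)
  # planted markers occupy the extreme |covariance| ranks
  top7 <- sp$peak_id[order(-abs(sp$covariance))][1:7]
  expect_setequal(top7, planted_marker_peaks)
})

test_that("label permutation degrades the model and is reproducible", {
  sim <- simulate_batch_set(seed = 1)
  X <- preprocess(sim$table)
  p1 <- permutation_test(X, sim$table$regions, n_perm = 50, seed = 2)
  p2 <- permutation_test(X, sim$table$regions, n_perm = 50, seed = 2)
  expect_identical(p1$permutations, p2$permutations)
  expect_true(all(p1$permutations$Q2 < p1$original$Q2))
  expect_lt(p1$q2_intercept, p1$original$Q2)
  # intercepts are stable across permutation seeds
  ints <- vapply(1:5, function(s) {
    permutation_test(X, sim$table$regions, n_perm = 200,
                     seed = s)$q2_intercept
  }, numeric(1))
  expect_lt(max(ints) - min(ints), 0.1)
})

test_that("noise-only labels give a flat permutation line", {
  q2_gap <- vapply(1:3, function(s) {
    set.seed(100 + s)
    X <- matrix(stats::rnorm(18 * 10), 18, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    y <- rep(c("a", "b"), each = 9)
    pt <- permutation_test(scale(X), y, n_perm = 50, seed = s)
    pt$q2_intercept - mean(pt$permutations$Q2)
  }, numeric(1))
  expect_lt(mean(abs(q2_gap)), 0.15)
})

test_that("marker selection enforces the VIP and p-value conjunction", {
  # identical groups: nothing selected
  set.seed(21)
  base <- matrix(stats::rlnorm(18 * 6), 18, 6,
                 dimnames = list(paste0("b", 1:18), paste0("p", 1:6)))
  pt_null <- peak_table(base, paste0("b", 1:18), paste0("p", 1:6),
                        regions = rep(c("HN", "HB"), each = 9))
  m_null <- oplsda(preprocess(pt_null), pt_null$regions)
  expect_false(any(select_markers(pt_null, m_null)$selected))
  # high VIP with a large p-value must not be selected
  fake <- structure(list(kind = "oplsda",
                         weights = stats::setNames(rep(1 / sqrt(6), 6),
                                                   paste0("p", 1:6)),
                         vip = stats::setNames(c(1.5, rep(0.9, 5)),
                                               paste0("p", 1:6))),
                    class = "latent_model")
  rep_null <- select_markers(pt_null, fake)
  row <- rep_null[rep_null$peak_id == "p1", ]
  expect_gt(row$vip, 1)
  expect_gt(row$p_value, 0.05)
  expect_false(row$selected)
})
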