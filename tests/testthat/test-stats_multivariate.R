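test_that("PCA recovers dominant axes, orthogonal scores, exact reconstruction", {
  # variance along a single axis
  m <- rbind(F1 = c(1, 2, 3, 4, 5), F2 = rep(2, 5), F3 = rep(7, 5))
  colnames(m) <- paste0("S", 1:5)
  fit <- pca_fit(peak_table(m), n_components = 2)
  expect_equal(fit$explained_variance[1], 1)

  set.seed(71)
  big <- tiny_pt(matrix(stats::rlnorm(80, 3), 8, 10))
  k <- min(dim(intensity_matrix(big)))  # full rank: exact reconstruction
  full <- pca_fit(big, n_components = k)
  g <- crossprod(full$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # reconstruction identity with all components
  recon <- full$scores %*% t(full$loadings)
  centred <- t(intensity_matrix(big)) -
    rep(rowMeans(intensity_matrix(big)), each = 10)
  expect_equal(unname(recon), unname(centred), tolerance = 1e-8)

  expect_error(pca_fit(big, n_components = 50), "n_components")
})

test_that("PLS-DA separates a strong single-feature effect and VIP is normalized", {
  set.seed(73)
  n <- 40
  m <- matrix(stats::rnorm(25 * n, 10), 25, n)
  m[1, 1:20] <- m[1, 1:20] + 5      # 5-sd effect in cases
  dimnames(m) <- list(paste0("F", 1:25), paste0("S", 1:n))
  meta <- sample_meta(paste0("S", 1:n), "1",
                      rep(c("case", "ctrl"), each = 20), 1:n)
  fit <- plsda_fit(peak_table(m), meta, seed = 5)
  # with a single informative feature carrying a d-sd shift and unit noise,
  # the predictable fraction of the +/-1 response is capped at
  # d^2/(d^2 + 4) ~= 0.86 for d = 5; Q2Y must approach that ceiling
  expect_gt(fit$q2y, 0.8)
  expect_gt(fit$r2y, fit$q2y - 0.05)
  expect_lte(fit$r2y, 1)
  expect_equal(which.max(fit$vip), c(F1 = 1))
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)

  # one component, two features with equal weights -> VIP = (1, 1)
  m2 <- rbind(F1 = c(1, 2, 3, 7, 8, 9), F2 = c(1, 2, 3, 7, 8, 9))
  colnames(m2) <- paste0("S", 1:6)
  meta2 <- sample_meta(paste0("S", 1:6), "1",
                       rep(c("a", "b"), each = 3), 1:6)
  fit2 <- plsda_fit(peak_table(m2), meta2, n_components = 1, cv_folds = 3)
  expect_equal(unname(fit2$vip), c(1, 1))
})

test_that("VIP normalization holds on random fits and matches mixOmics", {
  set.seed(79)
  for (i in 1:5) {
    n <- 16; p <- sample(5:30, 1)
    m <- matrix(stats::rnorm(p * n, 8), p, n,
                dimnames = list(paste0("F", 1:p), paste0("S", 1:n)))
    meta <- sample_meta(paste0("S", 1:n), "1",
                        rep(c("a", "b"), each = n / 2), 1:n)
    fit <- plsda_fit(peak_table(m), meta, n_components = 2, seed = i)
    expect_equal(sum(fit$vip^2), p, tolerance = 1e-8)
  }
  # independent implementation cross-check (never the implementation)
  set.seed(83)
  m <- matrix(stats::rnorm(200, 5), 20, 10,
              dimnames = list(paste0("F", 1:20), paste0("S", 1:10)))
  m[1:3, 1:5] <- m[1:3, 1:5] + 2
  meta <- sample_meta(paste0("S", 1:10), "1",
                      rep(c("a", "b"), each = 5), 1:10)
  fit <- plsda_fit(peak_table(m), meta, n_components = 2, cv_folds = 5)
  mo <- mixOmics::plsda(t(m), factor(meta$class), ncomp = 2, scale = FALSE)
  expect_gt(abs(stats::cor(fit$scores[, 1], mo$variates$X[, 1])), 0.999)
  vref <- mixOmics::vip(mo)[names(fit$vip), 2]
  expect_gt(stats::cor(fit$vip, vref), 0.999)
})

test_that("OPLS-DA reduces to PLS when no orthogonal structure exists", {
  # rank-one X aligned with y: nothing orthogonal to strip
  y <- rep(c(1, -1), each = 6)
  m <- outer(c(2, 1, 3), y) + 10
  dimnames(m) <- list(paste0("F", 1:3), paste0("S", 1:12))
  meta <- sample_meta(paste0("S", 1:12), "1",
                      rep(c("a", "b"), each = 6), 1:12)
  opls <- oplsda_fit(peak_table(m), meta, n_orthogonal = 1, cv_folds = 4)
  pls <- plsda_fit(peak_table(m), meta, n_components = 1, cv_folds = 4)
  cs <- abs(stats::cor(opls$scores[, "pred"], pls$scores[, 1]))
  expect_equal(cs, 1, tolerance = 1e-8)

  # orthogonal scores are uncorrelated with the response
  set.seed(89)
  m2 <- matrix(stats::rnorm(30 * 20, 10), 30, 20,
               dimnames = list(paste0("F", 1:30), paste0("S", 1:20)))
  m2[1:5, 1:10] <- m2[1:5, 1:10] + 3
  meta2 <- sample_meta(paste0("S", 1:20), "1",
                       rep(c("a", "b"), each = 10), 1:20)
  fit2 <- oplsda_fit(peak_table(m2), meta2, n_orthogonal = 1, seed = 2)
  expect_lt(abs(stats::cor(fit2$scores[, "orth1"], fit2$response)), 1e-8)
  # same seed reproduces Q2Y exactly
  fit3 <- oplsda_fit(peak_table(m2), meta2, n_orthogonal = 1, seed = 2)
  expect_identical(fit2$q2y, fit3$q2y)
})

test_that("permutation test bounds and detection of a real effect", {
  set.seed(97)
  m <- matrix(stats::rnorm(20 * 24, 10), 20, 24,
              dimnames = list(paste0("F", 1:20), paste0("S", 1:24)))
  m[1:4, 1:12] <- m[1:4, 1:12] + 4
  meta <- sample_meta(paste0("S", 1:24), "1",
                      rep(c("a", "b"), each = 12), 1:24)
  pr <- permutation_test(peak_table(m), meta, "plsda", n_perm = 39, seed = 3)
  expect_lte(pr$p_value, 0.05)
  expect_gte(pr$p_value, 1 / 40)  # minimum attainable p
  expect_equal(length(pr$q2y_permuted), 39)
  expect_error(permutation_test(peak_table(m), meta, "plsda", n_perm = 0),
               "n_perm")
})
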