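test_that("detection-rate filter applies QC and sample rules with strict <", {
  # 4 QCs + 10 experimental samples
  meta <- tiny_meta(rep(c("a", "b"), 5), n_qc = 4)
  m <- matrix(1, 3, 14, dimnames = list(paste0("F", 1:3), meta$sample))
  # F1: detected in 1/4 QCs (25% < 50%) but all samples -> removed
  m[1, paste0("QC", 2:4)] <- NA
  # F2: 2/4 QCs (50%, not < 50%), 2/10 samples (20%, not < 20%) -> kept
  m[2, paste0("QC", 3:4)] <- NA
  m[2, paste0("S", 3:10)] <- NA
  pt <- tiny_pt(m)
  filt <- filter_features(pt, meta)
  expect_identical(feature_ids(filt), c("F2", "F3"))
  # idempotent
  expect_identical(intensity_matrix(filter_features(filt, meta)),
                   intensity_matrix(filt))
  # fully observed table unchanged
  full <- tiny_pt(matrix(1:28, 2, 14,
                         dimnames = list(c("G1", "G2"), meta$sample)))
  expect_identical(feature_ids(filter_features(full, meta)), c("G1", "G2"))
})

test_that("without QCs only the experimental rule applies", {
  meta <- tiny_meta(rep("a", 10))
  m <- matrix(1, 2, 10, dimnames = list(c("F1", "F2"), meta$sample))
  m[1, 1:9] <- NA  # 10% < 20% -> removed
  filt <- filter_features(tiny_pt(m), meta)
  expect_identical(feature_ids(filt), "F2")
})

test_that("knn imputation follows the nearest-feature hand computation", {
  m <- rbind(f1 = c(1, 2, 3), f2 = c(1, 2, NA), f3 = c(10, 10, 10))
  colnames(m) <- paste0("S", 1:3)
  out <- impute_missing(peak_table(m), "knn", k = 1)
  expect_equal(intensity_matrix(out)["f2", "S3"], 3)
  expect_false(anyNA(intensity_matrix(out)))
})

test_that("imputation is identity on complete data and never alters observed cells", {
  set.seed(11)
  complete <- tiny_pt(matrix(stats::rlnorm(60, 5), 10, 6))
  for (method in c("knn", "svd", "rf", "min_half")) {
    expect_identical(intensity_matrix(impute_missing(complete, method)),
                     intensity_matrix(complete))
  }
  m <- intensity_matrix(complete)
  m[sample(length(m), 12)] <- NA
  holed <- tiny_pt(m)
  obs <- !is.na(m)
  for (method in c("knn", "svd", "rf", "min_half")) {
    out <- intensity_matrix(impute_missing(holed, method, seed = 3))
    expect_identical(out[obs], m[obs])
    expect_false(anyNA(out))
  }
})

test_that("rf imputation is reproducible under a fixed seed; bpca is reserved", {
  set.seed(12)
  m <- matrix(stats::rlnorm(80, 5), 10, 8)
  m[sample(80, 10)] <- NA
  pt <- tiny_pt(m)
  a <- intensity_matrix(impute_missing(pt, "rf", seed = 99))
  b <- intensity_matrix(impute_missing(pt, "rf", seed = 99))
  expect_identical(a, b)
  expect_error(impute_missing(pt, "bpca"), "not implemented")
  m[1, ] <- NA
  expect_error(impute_missing(tiny_pt(m), "knn"), "F1")
})

test_that("min_half imputes half the observed feature minimum", {
  m <- rbind(f1 = c(4, 8, NA))
  colnames(m) <- paste0("S", 1:3)
  out <- impute_missing(peak_table(m), "min_half")
  expect_equal(intensity_matrix(out)["f1", "S3"], 2)
})

test_that("glog and cube-root transforms match hand values", {
  pt <- tiny_pt(matrix(c(0, 3), 2, 1))
  g4 <- transform_intensities(pt, "glog", lambda = 4)
  expect_equal(intensity_matrix(g4)[1, 1], 0)  # (0 + 2)/2 = 1, log2 1 = 0
  g16 <- transform_intensities(pt, "glog", lambda = 16)
  expect_equal(intensity_matrix(g16)[2, 1], 2)  # (3 + 5)/2 = 4, log2 4 = 2
  # sign-preserving cube root via a centred (negative-valued) table
  ctr <- scale_features(tiny_pt(matrix(c(0, 8, 16), 1, 3)), "center")
  cr <- transform_intensities(ctr, "cube_root")
  expect_equal(as.numeric(intensity_matrix(cr)), c(-2, 0, 2))
  expect_error(transform_intensities(pt, "log"), "positive")
})

test_that("feature scaling matches hand computations and the auto identity", {
  pt <- tiny_pt(matrix(c(2, 4, 6), 1, 3))
  expect_equal(as.numeric(intensity_matrix(scale_features(pt, "auto"))),
               c(-1, 0, 1))
  expect_equal(as.numeric(intensity_matrix(scale_features(pt, "vast"))),
               c(-2, 0, 2))
  expect_equal(as.numeric(intensity_matrix(scale_features(pt, "range"))),
               c(-0.5, 0, 0.5))
  expect_equal(as.numeric(intensity_matrix(scale_features(pt, "pareto"))),
               c(-2, 0, 2) / sqrt(2))
  expect_equal(as.numeric(intensity_matrix(scale_features(pt, "level"))),
               c(-0.5, 0, 0.5))

  set.seed(5)
  big <- tiny_pt(matrix(stats::rlnorm(200, 6), 20, 10))
  sc <- intensity_matrix(scale_features(big, "auto"))
  expect_lt(max(abs(rowMeans(sc))), 1e-10)
  expect_lt(max(abs(apply(sc, 1, stats::sd) - 1)), 1e-10)

  const <- tiny_pt(rbind(c(2, 4, 6), c(5, 5, 5)))
  expect_warning(dropped <- scale_features(const, "auto"), "zero sd")
  expect_equal(n_features(dropped), 1)
  expect_error(scale_features(const, "auto", on_degenerate = "error"),
               "zero sd")
})

test_that("T2-ellipse outlier removal flags the displaced sample only", {
  set.seed(21)
  m <- matrix(stats::rnorm(40 * 21, 100), 40, 21,
              dimnames = list(paste0("F", 1:40), paste0("S", 1:21)))
  m[, 21] <- m[, 21] + 100  # ~100 cluster-sds along the mean direction
  pt <- tiny_pt(m)
  res <- remove_outliers(pt)
  expect_identical(res$removed$sample, "S21")
  expect_equal(res$removed$round, 1L)
  expect_equal(n_samples(res$final_table), 20)
  expect_lte(res$rounds_run, 3)

  # oracle: recompute T2 directly from a 2-component PCA of the input
  sc <- stats::prcomp(t(m), center = TRUE)
  t2 <- sc$x[, 1]^2 / stats::sd(sc$x[, 1])^2 +
    sc$x[, 2]^2 / stats::sd(sc$x[, 2])^2
  lim <- 2 * 20 / 19 * stats::qf(0.95, 2, 19)
  expect_equal(res$removed$t2, unname(t2["S21"]))
  expect_gt(res$removed$t2, lim)

  # tight cluster: no removals, one round
  clean <- tiny_pt(matrix(stats::rnorm(40 * 20, 100), 40, 20))
  res2 <- remove_outliers(clean)
  expect_equal(nrow(res2$removed), 0)

  # huge expansion: nothing ever removed; removals monotone in expand
  res3 <- remove_outliers(pt, expand = 1e6)
  expect_equal(nrow(res3$removed), 0)
  res4 <- remove_outliers(pt, expand = 1.5)
  expect_true(all(res4$removed$sample %in% res$removed$sample))
  expect_true(all(sample_ids(res$final_table) %in% sample_ids(pt)))
})
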