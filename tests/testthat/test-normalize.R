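test_that("sum normalization matches the hand-computed two-sample case", {
  pt <- tiny_pt(cbind(S1 = c(1, 2, 3), S2 = c(2, 4, 6)))
  out <- intensity_matrix(normalize_samples(pt, method = "sum"))
  expect_equal(unname(out[, "S1"]), c(1.5, 3, 4.5))  # median total 9
  expect_equal(unname(out[, "S2"]), c(1.5, 3, 4.5))
  # totals equal after normalization
  set.seed(2)
  big <- tiny_pt(matrix(stats::rlnorm(60, 5), 10, 6))
  tot <- colSums(intensity_matrix(normalize_samples(big, method = "sum")))
  expect_lt(diff(range(tot)) / tot[1], 1e-9)
})

test_that("PQN matches the hand case and recovers scalar multiples", {
  pt <- tiny_pt(cbind(S1 = c(2, 4, 6), S2 = c(1, 2, 3)))
  out <- intensity_matrix(normalize_samples(pt, method = "pqn"))
  expect_equal(unname(out[, "S1"]), c(1.5, 3, 4.5))  # all-sample median ref
  expect_equal(unname(out[, "S2"]), c(1.5, 3, 4.5))

  # samples that are exact scalar multiples of the reference collapse onto it
  set.seed(3)
  ref <- stats::rlnorm(20, 4)
  m <- vapply(c(0.5, 1, 2, 4), function(k) k * ref, numeric(20))
  colnames(m) <- paste0("S", 1:4); rownames(m) <- paste0("F", 1:20)
  outs <- intensity_matrix(normalize_samples(peak_table(m), method = "pqn",
                                             reference = ref))
  for (j in 1:4) expect_equal(unname(outs[, j]), unname(ref))
})

test_that("quantile normalization matches rank means, is idempotent, equalizes sorted vectors", {
  pt <- tiny_pt(cbind(S1 = c(2, 4), S2 = c(8, 6)))
  out <- intensity_matrix(normalize_samples(pt, method = "quantile"))
  expect_equal(unname(out[, "S1"]), c(4, 6))
  expect_equal(unname(out[, "S2"]), c(6, 4))

  set.seed(4)
  big <- tiny_pt(matrix(stats::rlnorm(120, 5), 20, 6))
  q1 <- intensity_matrix(normalize_samples(big, method = "quantile"))
  sorted <- apply(q1, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  q2 <- intensity_matrix(normalize_samples(tiny_pt(q1), method = "quantile"))
  expect_equal(q2, q1, tolerance = 1e-12)

  # independent oracle on complete matrices
  ref <- limma::normalizeQuantiles(intensity_matrix(big), ties = TRUE)
  expect_equal(unname(q1), unname(as.matrix(ref)), tolerance = 1e-10)
})

test_that("vsn is reserved and empty samples are rejected", {
  pt <- tiny_pt(cbind(S1 = c(1, 2), S2 = c(NA, NA)))
  expect_error(normalize_samples(tiny_pt(cbind(S1 = 1:2, S2 = 3:4)),
                                 method = "vsn"), "not implemented")
  expect_error(normalize_samples(pt, method = "sum"), "S2")
})

test_that("normalizations preserve the missing mask and matrix shape", {
  set.seed(6)
  m <- matrix(stats::rlnorm(80, 5), 10, 8)
  m[sample(80, 10)] <- NA
  meta <- sample_meta(paste0("S", 1:8), "1",
                      c(rep(c("a", "b"), 3), NA, NA), 1:8)
  pt <- tiny_pt(m)
  for (method in c("sum", "pqn", "quantile")) {
    out <- normalize_samples(pt, meta, method)
    expect_identical(is_missing(out), is_missing(pt))
    expect_identical(dim(intensity_matrix(out)), dim(m))
  }
})

test_that("QC CV filter removes high-CV features with <= boundary kept", {
  meta <- sample_meta(paste0("S", 1:5), "1",
                      c("a", "a", NA, NA, NA), 1:5)
  m <- rbind(F1 = c(5, 5, 1, 2, 3),        # QC CV = 0.5 > 0.30 -> removed
             F2 = c(5, 5, 10, 10, 10),     # QC CV = 0 -> kept
             F3 = c(5, 5, 7, 10, 13))      # QC CV = 0.3 exactly -> kept
  pt <- tiny_pt(m)
  expect_identical(feature_ids(cv_filter(pt, meta)), c("F2", "F3"))
  expect_equal(n_features(cv_filter(pt, meta, cv_max = Inf)), 3)
  no_qc <- sample_meta(paste0("S", 1:5), "1", rep("a", 5), 1:5)
  expect_error(cv_filter(pt, no_qc), "QC")
})

test_that("QC-RSC leaves drift-free data untouched and uses the fallback", {
  set.seed(7)
  sim <- simulate_peak_table(n_features = 20, n_case = 8, n_control = 8,
                             qc_every = 3, drift = "none", batch_sd = 0,
                             n_diff = 0, mnar_strength = 0, noise_sd = 0,
                             seed = 7)
  out <- qcrsc_correct(sim$peak_table, sim$meta)
  expect_equal(intensity_matrix(out), intensity_matrix(sim$peak_table),
               tolerance = 1e-8)

  # a batch with fewer QCs than min_qc falls back to median scaling
  sim2 <- simulate_peak_table(n_features = 5, n_case = 4, n_control = 4,
                              qc_every = 4, drift = "none", batch_sd = 0,
                              n_diff = 0, mnar_strength = 0, seed = 8)
  expect_message(
    qcrsc_correct(sim2$peak_table, sim2$meta,
                  min_qc = sum(sim2$meta$is_qc) + 1),
    "fallback")
})

test_that("QC-RSC and SVR remove injected injection-order drift", {
  sim <- simulate_peak_table(n_features = 120, n_case = 25, n_control = 25,
                             drift = "linear", drift_magnitude = 1,
                             batch_sd = 0, n_diff = 0, mnar_strength = 0,
                             noise_sd = 0.05, seed = 17)
  qc <- sim$meta$is_qc
  cv_of <- function(p) apply(intensity_matrix(p)[, qc], 1, compute_cv)
  pre <- cv_of(sim$peak_table)
  for (correct in list(qcrsc_correct, svr_correct)) {
    post <- cv_of(correct(sim$peak_table, sim$meta))
    expect_gte(mean(post < pre), 0.95)
    expect_lt(stats::median(post), stats::median(pre))
  }
})

test_that("SVR correction is deterministic and flat QC signal is identity", {
  sim <- simulate_peak_table(n_features = 30, n_case = 10, n_control = 10,
                             drift = "smooth", drift_magnitude = 0.4,
                             batch_sd = 0, n_diff = 0, mnar_strength = 0,
                             seed = 19)
  a <- intensity_matrix(svr_correct(sim$peak_table, sim$meta))
  b <- intensity_matrix(svr_correct(sim$peak_table, sim$meta))
  expect_identical(a, b)

  flat <- simulate_peak_table(n_features = 10, n_case = 8, n_control = 8,
                              qc_every = 3, drift = "none", batch_sd = 0,
                              n_diff = 0, mnar_strength = 0, noise_sd = 0,
                              seed = 20)
  out <- svr_correct(flat$peak_table, flat$meta)
  expect_equal(intensity_matrix(out), intensity_matrix(flat$peak_table),
               tolerance = 1e-8)
})

test_that("EB batch correction equalizes batch means in the symmetric case", {
  # every feature is a permutation of the same values, batch 2 offset by a
  # constant: the EB shrinkage target equals each estimate, so the
  # adjustment removes the offset exactly
  set.seed(23)
  base <- stats::rnorm(10, 10, 0.5)
  lg <- t(vapply(1:30, function(i) sample(base), numeric(10)))
  lg <- cbind(lg, lg[, sample(10)] + 2)
  dimnames(lg) <- list(paste0("F", 1:30), paste0("S", 1:20))
  meta <- sample_meta(paste0("S", 1:20), rep(c("1", "2"), each = 10),
                      rep(c("x", "y"), 10), 1:20)
  out <- log(intensity_matrix(combat_correct(peak_table(exp(lg)), meta)))
  b1 <- rowMeans(out[, 1:10]); b2 <- rowMeans(out[, 11:20])
  expect_lt(max(abs(b1 - b2) / abs(b1)), 1e-6)
})

test_that("EB batch correction removes injected batch variance and matches sva", {
  sim <- simulate_peak_table(n_features = 100, n_case = 15, n_control = 15,
                             drift = "none", batch_sd = 0.6,
                             mnar_strength = 0, n_diff = 0, seed = 11)
  pt <- sim$peak_table; meta <- sim$meta
  batch_var <- function(m) {
    bm <- vapply(unique(meta$batch),
                 function(b) rowMeans(m[, meta$batch == b]), numeric(nrow(m)))
    mean(apply(bm, 1, stats::var))
  }
  pre <- log(intensity_matrix(pt))
  post <- log(intensity_matrix(combat_correct(pt, meta)))
  expect_gte(1 - batch_var(post) / batch_var(pre), 0.95)

  ref <- sva::ComBat(dat = pre, batch = meta$batch)
  expect_gt(stats::cor(as.vector(post), as.vector(ref)), 0.99)

  # single batch: identity with a warning
  one <- sample_meta(meta$sample, "1", meta$class, meta$order)
  expect_warning(same <- combat_correct(pt, one), "single batch")
  expect_identical(intensity_matrix(same), intensity_matrix(pt))

  # label invariance: permuting samples and batches together commutes
  perm <- sample(n_samples(pt))
  pt_p <- pt[, perm]
  meta_p <- meta[match(sample_ids(pt_p), meta$sample), ]
  out_p <- combat_correct(pt_p, meta_p)
  out <- combat_correct(pt, meta)
  expect_equal(intensity_matrix(out_p),
               intensity_matrix(out)[, sample_ids(pt_p)])
})

test_that("normalization comparison reproduces the drift-correction ordering", {
  sim <- simulate_peak_table(n_features = 80, n_case = 15, n_control = 15,
                             drift = "smooth", drift_magnitude = 0.6,
                             batch_sd = 0.3, n_diff = 10, effect_log2 = 1,
                             mnar_strength = 0.5, seed = 31)
  cmp <- compare_normalizations(sim$peak_table, sim$meta,
                                methods = c("none", "pqn", "qcrsc", "svr"),
                                seed = 1)
  expect_setequal(cmp$method, c("none", "pqn", "qcrsc", "svr"))
  none <- cmp[cmp$method == "none", ]
  for (mth in c("qcrsc", "svr")) {
    row <- cmp[cmp$method == mth, ]
    expect_gt(row$n_peaks_cv_le, none$n_peaks_cv_le)
    expect_lt(row$mean_cv_QC, none$mean_cv_QC)
  }
  expect_true(all(cmp$n_peaks_cv_le <= cmp$n_peaks))
  expect_error(compare_normalizations(sim$peak_table, sim$meta,
                                      methods = c("none", "bogus")),
               "bogus")
})

test_that("drift-free comparison keeps nearly all peaks under the CV cut", {
  sim <- simulate_peak_table(n_features = 60, n_case = 12, n_control = 12,
                             drift = "none", batch_sd = 0, n_diff = 0,
                             mnar_strength = 0, noise_sd = 0.05, seed = 37)
  cmp <- compare_normalizations(sim$peak_table, sim$meta, methods = "none",
                                seed = 1)
  expect_gte(cmp$n_peaks_cv_le[1] / cmp$n_peaks[1], 0.95)
})
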