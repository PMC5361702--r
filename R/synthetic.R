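#' Simulate a multi-batch peak table with known ground truth
#'
#' Generates the data structure of a QC-anchored untargeted metabolomics
#' run so every pipeline stage can be exercised against known truth:
#'
#' * base feature abundances are log-normal (log2 means drawn uniformly in
#'   `log2_mean_range`, technical noise sd `noise_sd` on the log2 scale);
#' * case and control samples alternate across `n_batches` batches in a
#'   single injection sequence, with a pooled QC sample injected every
#'   `qc_every` positions (QC profiles are the pool mean plus the same
#'   measurement noise);
#' * multiplicative signal drift along injection order: `linear` applies
#'   `1 + drift_magnitude * (order/max_order)` scaled per batch, `smooth`
#'   a half-sine of amplitude `drift_magnitude` per batch, `none` nothing;
#' * additive per-feature batch offsets on the log2 scale, drawn
#'   `N(0, batch_sd^2)`;
#' * `n_diff` features are shifted by `effect_log2` (log2 units) in cases;
#' * intensity-dependent (missing-not-at-random) dropout: the missingness
#'   probability is logistic in the log2 intensity with slope
#'   `mnar_strength`, centred `mnar_center_sd` sds below the feature-mean
#'   distribution centre, so faint peaks drop out first. `mnar_strength = 0`
#'   disables missingness.
#'
#' Identical parameters and seed reproduce the output bit for bit.
#'
#' @param n_features,n_case,n_control Positive counts. Defaults 1000 /
#'   50 / 50.
#' @param n_batches Number of batches. Default 2.
#' @param qc_every A QC injection every this many positions (>= 2).
#'   Default 5.
#' @param drift `"none"`, `"linear"` or `"smooth"`.
#' @param drift_magnitude Relative drift amplitude. Default 0.3.
#' @param batch_sd Sd of log2 batch offsets. Default 0.5.
#' @param n_diff Number of differential features. Default 50.
#' @param effect_log2 Case-vs-control shift (log2). Default 1.
#' @param mnar_strength Dropout steepness (per log2 unit). Default 1.
#' @param mnar_center_sd How many feature-mean sds below the centre the
#'   50%-dropout point sits. Default 2.5.
#' @param noise_sd Technical noise sd (log2). Default 0.2.
#' @param log2_mean_range Range of feature log2 means. Default c(10, 20).
#' @param seed Integer seed.
#' @return A list of class `sim_peak_data`: `peak_table`, `meta`
#'   ([sample_meta()]) and `truth` (a list with the differential feature
#'   ids and effects, batch offsets, drift settings and seed).
#' @export
simulate_peak_table <- function(n_features = 1000, n_case = 50,
                                n_control = 50, n_batches = 2, qc_every = 5,
                                drift = c("smooth", "linear", "none"),
                                drift_magnitude = 0.3, batch_sd = 0.5,
                                n_diff = 50, effect_log2 = 1,
                                mnar_strength = 1, mnar_center_sd = 2.5,
                                noise_sd = 0.2,
                                log2_mean_range = c(10, 20), seed = 1L) {
  drift <- match.arg(drift)
  stopifnot(n_features >= 1, n_case >= 1, n_control >= 1, n_batches >= 1,
            qc_every >= 2, n_diff >= 0, n_diff <= n_features,
            drift_magnitude >= 0, batch_sd >= 0, noise_sd >= 0,
            mnar_strength >= 0)
  set.seed(seed)

  feature_ids <- sprintf("F%04d", seq_len(n_features))
  base_log2 <- stats::runif(n_features, log2_mean_range[1],
                            log2_mean_range[2])
  mz <- stats::runif(n_features, 80, 1200)
  rt <- stats::runif(n_features, 0.5, 20)

  # interleave cases and controls, then insert QCs every qc_every positions
  exp_class <- sample(rep(c("case", "control"), times = c(n_case, n_control)))
  classes <- character(0)
  k <- 0
  for (i in seq_along(exp_class)) {
    if (k %% (qc_every - 1) == 0) classes <- c(classes, NA_character_)
    classes <- c(classes, exp_class[i])
    k <- k + 1
  }
  classes <- c(classes, NA_character_)  # closing QC
  n_total <- length(classes)
  batch <- as.character(rep(seq_len(n_batches),
                            each = ceiling(n_total / n_batches))[seq_len(n_total)])
  sample_id <- ifelse(is.na(classes),
                      sprintf("QC%03d", cumsum(is.na(classes))),
                      sprintf("S%03d", cumsum(!is.na(classes))))
  meta <- sample_meta(sample_id, batch, classes, seq_len(n_total))

  diff_ids <- if (n_diff > 0) sort(sample(feature_ids, n_diff)) else character(0)
  effect <- stats::setNames(rep(0, n_features), feature_ids)
  effect[diff_ids] <- effect_log2
  batch_offsets <- matrix(stats::rnorm(n_features * n_batches, 0, batch_sd),
                          n_features, n_batches,
                          dimnames = list(feature_ids, NULL))

  lg <- matrix(base_log2, n_features, n_total)
  is_case <- !is.na(classes) & classes == "case"
  lg[, is_case] <- lg[, is_case] + effect
  for (b in seq_len(n_batches)) {
    cols <- batch == as.character(b)
    lg[, cols] <- lg[, cols] + batch_offsets[, b]
  }
  lg <- lg + matrix(stats::rnorm(n_features * n_total, 0, noise_sd),
                    n_features, n_total)

  drift_curve <- matrix(0, n_features, n_total)
  if (drift != "none" && drift_magnitude > 0) {
    for (b in seq_len(n_batches)) {
      cols <- which(batch == as.character(b))
      pos <- (meta$order[cols] - min(meta$order[cols])) /
        max(1, diff(range(meta$order[cols])))
      fac <- switch(drift,
        linear = 1 + drift_magnitude * pos,
        smooth = 1 + drift_magnitude * sin(pi * pos))
      drift_curve[, cols] <- matrix(log2(fac), n_features, length(cols),
                                    byrow = TRUE)
    }
    lg <- lg + drift_curve
  }

  intens <- 2^lg
  if (mnar_strength > 0) {
    centre <- mean(base_log2) - mnar_center_sd * stats::sd(base_log2)
    p_miss <- stats::plogis(-(lg - centre) * mnar_strength)
    drop <- matrix(stats::runif(length(lg)) < p_miss, n_features, n_total)
    # never silence a feature entirely
    all_gone <- rowSums(!drop) == 0
    drop[all_gone, 1] <- FALSE
    intens[drop] <- NA_real_
  }
  dimnames(intens) <- list(feature_ids, sample_id)

  structure(list(
    peak_table = peak_table(intens, mz = mz, rt = rt),
    meta = meta,
    truth = list(diff_features = diff_ids, effect_log2 = effect_log2,
                 effects = effect, batch_offsets = batch_offsets,
                 drift = drift, drift_magnitude = drift_magnitude,
                 drift_log2 = drift_curve, noise_sd = noise_sd,
                 mnar_strength = mnar_strength, seed = seed)
  ), class = "sim_peak_data")
}

#' @export
print.sim_peak_data <- function(x, ...) {
  cat("<sim_peak_data> ", n_features(x$peak_table), " features x ",
      n_samples(x$peak_table), " samples (",
      sum(x$meta$is_qc), " QCs); ", length(x$truth$diff_features),
      " differential feature(s)\n", sep = "")
  invisible(x)
}
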