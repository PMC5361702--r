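#' Sample-based normalization
#'
#' @description
#' Corrects per-sample concentration/dilution differences. Missing cells are
#' ignored in all statistics and stay missing.
#'
#' * `sum` — each sample is divided by its observed total intensity and
#'   multiplied by the median of all sample totals (so the output stays on
#'   the original intensity scale).
#' * `pqn` — probabilistic quotient normalization: the reference spectrum is
#'   the feature-wise median over QC samples (falling back to all samples
#'   when no QCs exist or `meta` is absent); each sample is divided by the
#'   median of its per-feature quotients against the reference.
#' * `quantile` — classic rank/mean substitution: each sample's values are
#'   replaced by the mean across samples of the values at the same rank;
#'   ties receive the mean of their tied rank values.
#' * `vsn` — reserved; raises a not-implemented error.
#'
#' @param pt A [peak_table()].
#' @param meta Optional [sample_meta()] (used by `pqn` to find QCs).
#' @param method `"sum"`, `"pqn"`, `"quantile"` or `"vsn"`.
#' @param reference Optional explicit reference spectrum for `pqn` (one
#'   value per feature); overrides the QC/all-sample median.
#' @return The normalized [peak_table()].
#' @export
normalize_samples <- function(pt, meta = NULL,
                              method = c("sum", "pqn", "quantile", "vsn"),
                              reference = NULL) {
  method <- match.arg(method)
  if (method == "vsn") {
    stop("VSN normalization is not implemented; use sum, pqn or quantile",
         call. = FALSE)
  }
  m <- intensity_matrix(pt)
  empty <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(empty)) {
    stop("sample(s) with no observed values: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- switch(method,
    sum = {
      totals <- colSums(m, na.rm = TRUE)
      sweep(m, 2, totals, "/") * stats::median(totals)
    },
    pqn = {
      ref <- if (!is.null(reference)) {
        stopifnot(length(reference) == nrow(m))
        ifelse(reference == 0, NA_real_, reference)
      } else pqn_reference(m, meta)
      quot <- m / ref
      factors <- apply(quot, 2, stats::median, na.rm = TRUE)
      if (anyNA(factors) || any(factors == 0)) {
        stop("PQN dilution factor undefined for some sample(s)", call. = FALSE)
      }
      sweep(m, 2, factors, "/")
    },
    quantile = quantile_normalize(m)
  )
  set_intensities(pt, out)
}

pqn_reference <- function(m, meta) {
  if (!is.null(meta)) {
    idx <- match(colnames(m), meta$sample)
    qc <- !is.na(idx) & meta$is_qc[idx]
    qc[is.na(qc)] <- FALSE
    if (sum(qc) >= 2) {
      ref <- apply(m[, qc, drop = FALSE], 1, stats::median, na.rm = TRUE)
      ref[is.nan(ref) | ref == 0] <- NA_real_
      return(ref)
    }
  }
  ref <- apply(m, 1, stats::median, na.rm = TRUE)
  ref[is.nan(ref) | ref == 0] <- NA_real_
  ref
}

# Rank-mean quantile normalization with mean-of-tied-ranks ties and
# mask preservation. The reference distribution is the row-mean of the
# per-sample sorted observed values; samples with missing cells use the
# quantiles of their own observed ranks (interpolated against the reference).
quantile_normalize <- function(m) {
  n_obs <- colSums(!is.na(m))
  ref_len <- max(n_obs)
  # reference: mean across samples of sorted values, each sample's sorted
  # vector stretched to ref_len by linear interpolation (exact when complete)
  sorted <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[!is.na(m[, j]), j])
    if (length(v) == ref_len) v
    else stats::approx(seq(0, 1, length.out = length(v)), v,
                       seq(0, 1, length.out = ref_len))$y
  }, numeric(ref_len))
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    obs <- !is.na(m[, j])
    k <- sum(obs)
    rk <- rank(m[obs, j], ties.method = "average")
    vals <- if (k == ref_len) ref
            else stats::approx(seq(0, 1, length.out = ref_len), ref,
                               seq(0, 1, length.out = k))$y
    # mean-of-tied-ranks: average rank maps to linear interpolation on vals
    out[obs, j] <- stats::approx(seq_len(k), vals, rk)$y
  }
  out
}

#' QC coefficient-of-variation filter
#'
#' Removes features whose coefficient of variation over the observed QC
#' intensities exceeds `cv_max` (strictly; a feature at exactly the
#' threshold is kept). Intended to run after normalization.
#'
#' @param pt A [peak_table()].
#' @param meta [sample_meta()] with QC samples flagged.
#' @param cv_max Maximum tolerated QC CV as a fraction. Default 0.30.
#' @return The filtered [peak_table()].
#' @export
cv_filter <- function(pt, meta, cv_max = 0.30) {
  meta <- align_meta(pt, meta)
  if (!any(meta$is_qc)) stop("no QC samples; CV filter requires QCs",
                             call. = FALSE)
  qc <- intensity_matrix(pt)[, meta$is_qc, drop = FALSE]
  cv <- apply(qc, 1, function(x) compute_cv(x[!is.na(x)]))
  keep <- is.na(cv) | cv <= cv_max
  pt[keep, ]
}

#' Compare normalization strategies
#'
#' Applies each candidate method (always including the `"none"` baseline) to
#' the same peak table and reports, per method: the number of peaks, the
#' number of peaks with QC CV at or below `cv_max`, the mean CV per group
#' (QC and each experimental class), and the number of differentially
#' expressed features (DEF). A DEF satisfies q <= `def_q` (BH-adjusted
#' Mann-Whitney by default, `test = "t"` for the t-test), fold change >=
#' `def_fc` or <= 1/`def_fc`, and PLS-DA VIP >= `def_vip`; the VIP comes from
#' a two-component PLS-DA fit on the glog + Pareto version of each
#' normalized table.
#'
#' @param pt A raw (unnormalized, filtered/imputable) [peak_table()].
#' @param meta [sample_meta()] with exactly two experimental classes.
#' @param methods Character vector of method names among
#'   `"none"`, `"sum"`, `"pqn"`, `"quantile"`, `"qcrsc"`, `"svr"`, `"combat"`.
#' @param case,control The two class labels compared for DEF counting;
#'   defaults to the two classes in `meta` (first as case).
#' @param def_q,def_fc,def_vip DEF thresholds. Defaults 0.05 / 1.5 / 1.0.
#' @param cv_max QC CV threshold. Default 0.30.
#' @param test `"wilcox"` (default) or `"t"` for the DEF q-value.
#' @param seed Seed for the PLS-DA cross-validation split.
#' @return A `normalization_comparison` tibble: one row per method with
#'   columns `method`, `n_peaks`, `n_peaks_cv_le`, `n_def` and `mean_cv_<group>`.
#' @export
compare_normalizations <- function(pt, meta, methods = c("none", "sum", "pqn",
                                                         "quantile", "qcrsc",
                                                         "svr", "combat"),
                                   case = NULL, control = NULL,
                                   def_q = 0.05, def_fc = 1.5, def_vip = 1.0,
                                   cv_max = 0.30, test = c("wilcox", "t"),
                                   seed = 1L) {
  test <- match.arg(test)
  valid <- c("none", "sum", "pqn", "quantile", "qcrsc", "svr", "combat")
  unknown <- setdiff(methods, valid)
  if (length(unknown)) {
    stop("unknown normalization method(s): ", paste(unknown, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  methods <- union("none", methods)
  meta_al <- align_meta(pt, meta)
  classes <- sort(unique(stats::na.omit(meta_al$class)))
  if (is.null(case) || is.null(control)) {
    if (length(classes) != 2) {
      stop("need exactly two experimental classes for DEF counting",
           call. = FALSE)
    }
    case <- classes[1]; control <- classes[2]
  }
  rows <- lapply(methods, function(mth) {
    norm <- apply_normalization(pt, meta_al, mth)
    qc_cv <- group_mean_cvs(norm, meta_al)
    uni <- univariate_tests(impute_missing(norm, "min_half"), meta_al,
                            case = case, control = control, seed = seed,
                            vip = TRUE)
    p_col <- if (test == "wilcox") uni$p_wilcox else uni$p_t
    q <- bh_adjust(p_col)
    def <- sum(q <= def_q &
                 (uni$fold_change >= def_fc | uni$fold_change <= 1 / def_fc) &
                 uni$vip >= def_vip, na.rm = TRUE)
    cvs <- apply(intensity_matrix(norm)[, meta_al$is_qc, drop = FALSE], 1,
                 function(x) compute_cv(x[!is.na(x)]))
    out <- tibble::tibble(method = mth, n_peaks = n_features(norm),
                          n_peaks_cv_le = sum(cvs <= cv_max, na.rm = TRUE),
                          n_def = def)
    dplyr::bind_cols(out, qc_cv)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("normalization_comparison", class(out))
  out
}

apply_normalization <- function(pt, meta, method) {
  switch(method,
    none = pt,
    sum = normalize_samples(pt, meta, "sum"),
    pqn = normalize_samples(pt, meta, "pqn"),
    quantile = normalize_samples(pt, meta, "quantile"),
    qcrsc = qcrsc_correct(pt, meta),
    svr = svr_correct(pt, meta),
    combat = combat_correct(pt, meta)
  )
}

group_mean_cvs <- function(pt, meta) {
  m <- intensity_matrix(pt)
  groups <- c(list(QC = meta$is_qc),
              stats::setNames(
                lapply(sort(unique(stats::na.omit(meta$class))),
                       function(g) !is.na(meta$class) & meta$class == g),
                sort(unique(stats::na.omit(meta$class)))))
  vals <- lapply(groups, function(sel) {
    if (sum(sel) < 2) return(NA_real_)
    cvs <- apply(m[, sel, drop = FALSE], 1,
                 function(x) compute_cv(x[!is.na(x)]))
    mean(cvs, na.rm = TRUE)
  })
  tibble::as_tibble(stats::setNames(vals, paste0("mean_cv_", names(groups))))
}
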