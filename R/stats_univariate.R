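#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} ( p_(j) * m / j )`, mapped back to input order.
#'
#' @param pvals Numeric p-values in \[0, 1\] (`NA` allowed and propagated).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Univariate ROC AUC
#'
#' Area under the ROC curve for separating case from control scores,
#' computed by pair counting: the fraction of (case, control) pairs where
#' the case scores higher, ties counted one half (the normalized
#' Mann-Whitney U statistic).
#'
#' @param scores_case,scores_control Numeric score vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' univariate_auc(c(3, 1), c(2, 0))  # 0.75
univariate_auc <- function(scores_case, scores_control) {
  scores_case <- scores_case[!is.na(scores_case)]
  scores_control <- scores_control[!is.na(scores_control)]
  n1 <- length(scores_case); n2 <- length(scores_control)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(scores_case, scores_control), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Per-feature two-group univariate statistics
#'
#' For every feature: two-sided t-test (Welch by default), two-sided
#' Mann-Whitney U test (exact enumeration when `n1 + n2 <= 12` and no ties,
#' otherwise the normal approximation with continuity and tie correction),
#' BH q-values per test family, fold change (case mean / control mean on the
#' intensity scale given), ROC AUC, and optionally the PLS-DA VIP. QC
#' samples are always excluded. Features with fewer than two observed values
#' in either group are marked untestable (`NA` statistics).
#'
#' @param pt A [peak_table()] (normalized, untransformed intensities; fold
#'   changes are computed on this scale).
#' @param meta [sample_meta()].
#' @param case,control Class labels compared (fold change = case / control).
#' @param welch Welch t-test (default) or pooled-variance with
#'   `welch = FALSE`.
#' @param test Which test's q-value fills the `q` column: `"wilcox"`
#'   (default) or `"t"`. Both families are always reported.
#' @param vip Attach the VIP from a 2-component PLS-DA fitted on the
#'   glog + Pareto version of the table? Default `TRUE`.
#' @param seed Seed for the PLS-DA cross-validation split.
#' @return A `univariate_result` tibble: `feature_id`, `n_case`,
#'   `n_control`, `p_t`, `p_wilcox`, `q_t`, `q_wilcox`, `q`, `fold_change`,
#'   `auc`, `vip`.
#' @export
univariate_tests <- function(pt, meta, case, control, welch = TRUE,
                             test = c("wilcox", "t"), vip = TRUE, seed = 1L) {
  test <- match.arg(test)
  meta <- align_meta(pt, meta)
  for (g in c(case, control)) {
    if (!g %in% meta$class) {
      stop("group label not present in sample metadata: ", g, call. = FALSE)
    }
  }
  m <- intensity_matrix(pt)
  a <- !is.na(meta$class) & meta$class == case
  b <- !is.na(meta$class) & meta$class == control
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    x <- m[i, a]; x <- x[!is.na(x)]
    y <- m[i, b]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(n_case = length(x), n_control = length(y),
                            p_t = NA_real_, p_wilcox = NA_real_,
                            fold_change = NA_real_, auc = NA_real_))
    }
    p_t <- if (stats::sd(c(x, y)) == 0) 1 else {
      tryCatch(stats::t.test(x, y, var.equal = !welch)$p.value,
               error = function(e) NA_real_)
    }
    exact <- length(x) + length(y) <= 12 && !anyDuplicated(c(x, y))
    p_w <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    tibble::tibble(n_case = length(x), n_control = length(y),
                   p_t = p_t, p_wilcox = p_w,
                   fold_change = mean(x) / mean(y),
                   auc = univariate_auc(x, y))
  })
  res <- dplyr::bind_cols(tibble::tibble(feature_id = feature_ids(pt)), res)
  res$q_t <- bh_adjust(res$p_t)
  res$q_wilcox <- bh_adjust(res$p_wilcox)
  res$q <- if (test == "wilcox") res$q_wilcox else res$q_t
  res$vip <- if (vip) {
    vip_for_table(pt, meta, case, control, seed = seed)
  } else NA_real_
  class(res) <- c("univariate_result", class(res))
  res
}

# VIP from a 2-component PLS-DA on the glog + Pareto preset of `pt`.
vip_for_table <- function(pt, meta, case, control, seed) {
  prep <- impute_missing(pt, "min_half")
  if (all(intensity_matrix(prep) >= 0, na.rm = TRUE)) {
    prep <- transform_intensities(prep, "glog")
  }
  prep <- scale_features(prep, "pareto")
  fit <- plsda_fit(prep, meta, case = case, control = control,
                   n_components = 2, seed = seed)
  fit$vip[match(feature_ids(pt), names(fit$vip))]
}

#' Select differentially expressed features (DEF)
#'
#' A feature is selected when q <= `q_max`, fold change >= `fc_min` or
#' <= 1/`fc_min`, and VIP >= `vip_min`. Following the field's reporting
#' convention, fold changes and the 1/`fc_min` bound are compared after
#' rounding to three decimals (so with `fc_min = 1.5` the lower bound
#' applied is 0.667).
#'
#' @param res A `univariate_result` from [univariate_tests()].
#' @param q_max,fc_min,vip_min Selection thresholds. Defaults 0.05 / 1.5 / 1.
#' @return The selected subset of `res`, ordered by q.
#' @export
select_def <- function(res, q_max = 0.05, fc_min = 1.5, vip_min = 1.0) {
  fc <- round(res$fold_change, 3)
  keep <- !is.na(res$q) & res$q <= q_max &
    (fc >= round(fc_min, 3) | fc <= round(1 / fc_min, 3)) &
    !is.na(res$vip) & res$vip >= vip_min
  out <- res[keep, , drop = FALSE]
  out[order(out$q), , drop = FALSE]
}

#' @export
glance.univariate_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_testable = sum(!is.na(x$q)),
    n_q_le_05 = sum(x$q <= 0.05, na.rm = TRUE),
    min_q = suppressWarnings(min(x$q, na.rm = TRUE))
  )
}
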