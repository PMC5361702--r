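#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Returns `NA` for fewer than two values or a zero mean; the CV is reported
#' as a fraction (multiply by 100 for percent).
#'
#' @param values Numeric vector of observed values.
#' @return A single numeric CV, or `NA`.
#' @export
#' @examples
#' compute_cv(c(1, 2, 3))   # 0.5
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

#' Per-sample quality summaries
#'
#' The data series behind the per-sample quality charts: detected-feature
#' count, missing count and total observed intensity per sample, ordered by
#' injection order and annotated with batch and group.
#'
#' @param pt A [peak_table()].
#' @param meta [sample_meta()] covering the samples.
#' @return A tibble with one row per sample: `sample`, `batch`, `class`,
#'   `is_qc`, `order`, `detected`, `missing`, `total_intensity`.
#' @export
sample_summaries <- function(pt, meta) {
  meta <- align_meta(pt, meta)
  m <- intensity_matrix(pt)
  out <- tibble::tibble(
    sample = sample_ids(pt),
    batch = meta$batch,
    class = meta$class,
    is_qc = meta$is_qc,
    order = meta$order,
    detected = unname(colSums(!is.na(m))),
    missing = unname(colSums(is.na(m))),
    total_intensity = unname(colSums(m, na.rm = TRUE))
  )
  dplyr::arrange(out, .data$order)
}

#' Feature m/z vs retention-time series
#'
#' @param pt A [peak_table()].
#' @return A tibble `feature_id`, `mz`, `rt`, `detected` (sample count) for
#'   the m/z distribution and m/z-vs-RT charts.
#' @export
feature_summaries <- function(pt) {
  fd <- feature_data(pt)
  tibble::tibble(feature_id = fd$feature_id, mz = fd$mz, rt = fd$rt,
                 detected = rowSums(!is_missing(pt)))
}

#' QC-sample correlation matrix
#'
#' Pairwise correlation between QC samples over pairwise-complete observed
#' features.
#'
#' @param pt A [peak_table()].
#' @param meta [sample_meta()].
#' @param method `"pearson"` or `"spearman"`.
#' @return A symmetric correlation matrix over the QC samples.
#' @export
qc_correlation <- function(pt, meta, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  meta <- align_meta(pt, meta)
  if (sum(meta$is_qc) < 2) stop("need at least 2 QC samples", call. = FALSE)
  qc <- intensity_matrix(pt)[, meta$is_qc, drop = FALSE]
  stats::cor(qc, use = "pairwise.complete.obs", method = method)
}

#' Per-feature CV before vs after normalization
#'
#' @param pt_pre,pt_post Peak tables before and after normalization; the
#'   feature intersection is used.
#' @param meta [sample_meta()].
#' @return A tibble `feature_id`, `group`, `cv_pre`, `cv_post`, one row per
#'   feature per group with at least two observed values (groups with fewer
#'   than two samples are excluded). QC samples form the `"QC"` group.
#' @export
cv_distribution <- function(pt_pre, pt_post, meta) {
  common <- intersect(feature_ids(pt_pre), feature_ids(pt_post))
  pre <- intensity_matrix(pt_pre)[common, , drop = FALSE]
  post <- intensity_matrix(pt_post)[common, , drop = FALSE]
  meta_pre <- align_meta(pt_pre, meta)
  grp <- ifelse(meta_pre$is_qc, "QC", meta_pre$class)
  rows <- lapply(unique(grp), function(g) {
    sel <- grp == g
    if (sum(sel) < 2) return(NULL)
    tibble::tibble(
      feature_id = common,
      group = g,
      cv_pre = apply(pre[, sample_ids(pt_pre)[sel], drop = FALSE], 1,
                     function(x) compute_cv(x[!is.na(x)])),
      cv_post = apply(post[, intersect(sample_ids(pt_post),
                                       sample_ids(pt_pre)[sel]),
                           drop = FALSE], 1,
                      function(x) compute_cv(x[!is.na(x)]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Full quality-assessment bundle
#'
#' Computes every chart data series at once: per-sample summaries, the
#' missing-value distribution, the QC correlation matrix (when >= 2 QCs),
#' feature m/z / RT series, and 2-component PCA scores of the (min-half
#' imputed, glog, Pareto-scaled) table.
#'
#' @param pt A [peak_table()].
#' @param meta [sample_meta()].
#' @return A list of class `qa_summary` with elements `samples`, `features`,
#'   `qc_correlation` (or `NULL`), `pca_scores`.
#' @export
qa_summary <- function(pt, meta) {
  meta_al <- align_meta(pt, meta)
  prepped <- pt |>
    impute_missing("min_half") |>
    transform_intensities("glog") |>
    scale_features("pareto")
  pca <- pca_fit(prepped, n_components = 2)
  scores <- tibble::as_tibble(pca$scores, rownames = "sample")
  scores$batch <- meta_al$batch
  scores$class <- ifelse(meta_al$is_qc, "QC", meta_al$class)
  structure(list(
    samples = sample_summaries(pt, meta),
    features = feature_summaries(pt),
    qc_correlation = if (sum(meta_al$is_qc) >= 2) qc_correlation(pt, meta),
    pca_scores = scores
  ), class = "qa_summary")
}

#' @export
print.qa_summary <- function(x, ...) {
  cat("<qa_summary> ", nrow(x$samples), " samples, ", nrow(x$features),
      " features", if (!is.null(x$qc_correlation))
        paste0(", ", nrow(x$qc_correlation), " QCs"), "\n", sep = "")
  invisible(x)
}
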