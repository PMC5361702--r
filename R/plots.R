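#' Plot per-sample QC series
#'
#' Line/point chart of a per-sample statistic against injection order,
#' coloured by group and shaped by batch.
#'
#' @param summaries Output of [sample_summaries()].
#' @param y One of `"total_intensity"`, `"detected"`, `"missing"`.
#' @return A ggplot object.
#' @export
plot_sample_series <- function(summaries, y = c("total_intensity",
                                                "detected", "missing")) {
  y <- match.arg(y)
  grp <- ifelse(summaries$is_qc, "QC", summaries$class)
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$order,
                                          y = .data[[y]],
                                          colour = grp,
                                          shape = .data$batch)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injection order", y = y, colour = "group",
                  shape = "batch") +
    ggplot2::theme_minimal()
}

#' Plot a CV distribution comparison
#'
#' Density of per-feature CVs before and after normalization, per group.
#'
#' @param cvs Output of [cv_distribution()].
#' @return A ggplot object.
#' @export
plot_cv_distribution <- function(cvs) {
  long <- tidyr::pivot_longer(cvs, c("cv_pre", "cv_post"),
                              names_to = "stage", values_to = "cv")
  long$stage <- ifelse(long$stage == "cv_pre", "before", "after")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cv, colour = .data$stage)) +
    ggplot2::geom_density(na.rm = TRUE) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "coefficient of variation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Score plot of a multivariate model
#'
#' @param object A `multivariate_model` from [pca_fit()], [plsda_fit()] or
#'   [oplsda_fit()].
#' @param ... Unused.
#' @return A ggplot scatter of the first two score columns.
#' @export
autoplot.multivariate_model <- function(object, ...) {
  sc <- tidy(object)
  cols <- setdiff(names(sc), c("sample", "group"))
  if (length(cols) < 2) stop("need at least two score columns", call. = FALSE)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[cols[1]]],
                                        y = .data[[cols[2]]]))
  p <- if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else p + ggplot2::geom_point()
  p + ggplot2::labs(title = toupper(object$kind)) + ggplot2::theme_minimal()
}

#' Power-curve plot
#'
#' @param object A `power_curve` from [estimate_power()].
#' @param ... Unused.
#' @return A ggplot of estimated power against per-group sample size.
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_per_group,
                                       y = .data$estimated_power)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "samples per group", y = "estimated power") +
    ggplot2::theme_minimal()
}

#' ROC-curve plot
#'
#' @param object An `evaluation_result` from [evaluate_model()].
#' @param ... Unused.
#' @return A ggplot ROC curve annotated with the AUROC.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Permutation-test plot
#'
#' Histogram of permuted Q2Y values with the observed value marked.
#'
#' @param object A `permutation_result` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble::tibble(q2y = object$q2y_permuted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q2y)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$q2y_observed, colour = "red") +
    ggplot2::labs(x = "permuted Q2Y",
                  title = sprintf("permutation p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}
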