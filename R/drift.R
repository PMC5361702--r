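#' QC-based robust spline drift/batch correction (QC-RSC)
#'
#' For every feature and batch, fits a cubic smoothing spline to the
#' log-intensities of the QC samples against injection order. The smoothing
#' parameter is chosen per curve by leave-one-out cross-validation over a
#' grid of 20 log-spaced penalty values (ties broken toward the smoother
#' fit). The fitted drift curve, evaluated at each sample's injection order
#' (clamped to the range spanned by the batch's QC injections), is
#' subtracted on the log scale and the signal re-anchored to the feature's
#' overall QC median, so per-batch curves also remove batch-to-batch
#' offsets:
#' `corrected = exp(log x - fit(order) + median(log x_QC))`.
#'
#' A feature/batch with fewer than `min_qc` observed QC points falls back to
#' QC-median scaling (a constant drift curve); missing cells stay missing.
#'
#' @param pt A [peak_table()] of positive intensities.
#' @param meta [sample_meta()] with QC flags, batches and injection order.
#' @param min_qc Minimum QC points per feature/batch for a spline fit.
#'   Default 4.
#' @param lambda_grid Candidate smoothing penalties; default
#'   `10^seq(-4, 2, length.out = 20)`.
#' @return The corrected [peak_table()].
#' @export
qcrsc_correct <- function(pt, meta, min_qc = 4,
                          lambda_grid = 10^seq(-4, 2, length.out = 20)) {
  correct_drift(pt, meta, min_qc, fit_fun = function(x, y) {
    fit <- loocv_spline(x, y, lambda_grid)
    function(newx) stats::predict(fit, pmin(pmax(newx, min(x)), max(x)))$y
  })
}

# Choose smoothing penalty by exact leave-one-out CV (leverage identity via
# smooth.spline's cv.crit at fixed lambda); prefer the largest lambda among
# near-ties.
loocv_spline <- function(x, y, lambda_grid) {
  grid <- sort(lambda_grid, decreasing = TRUE)  # smoother first
  best <- NULL; best_cv <- Inf
  for (lam in grid) {
    fit <- try(suppressWarnings(
      stats::smooth.spline(x, y, lambda = lam, cv = TRUE, keep.data = FALSE)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.finite(fit$cv.crit) && fit$cv.crit < best_cv - 1e-12) {
      best_cv <- fit$cv.crit; best <- fit
    }
  }
  if (is.null(best)) {
    # degenerate geometry: fall back to a linear fit wrapped as predictor
    lf <- stats::lm(y ~ x)
    return(structure(list(lm = lf), class = "linear_drift"))
  }
  best
}

#' @export
predict.linear_drift <- function(object, x, ...) {
  list(y = unname(stats::predict(object$lm, data.frame(x = x))))
}

#' Support-vector-regression drift correction
#'
#' Per feature (and per batch when several batches are present), trains an
#' RBF-kernel epsilon-SVR of QC log-intensity on injection order and
#' subtracts the predicted drift on the log scale, re-anchoring to the
#' feature's overall QC median exactly as in [qcrsc_correct()]. Features
#' whose QC intensities are constant are returned unchanged (no drift to
#' remove). Deterministic given identical inputs.
#'
#' @param pt A [peak_table()] of positive intensities.
#' @param meta [sample_meta()].
#' @param min_qc Minimum QC points per feature/batch; below it the QC-median
#'   fallback is used. Default 4.
#' @param gamma RBF kernel width; `NULL` uses the `e1071::svm` default on
#'   scaled inputs.
#' @param epsilon SVR epsilon-tube width. Default 0.1.
#' @param cost SVR cost. Default 1.
#' @return The corrected [peak_table()].
#' @export
svr_correct <- function(pt, meta, min_qc = 4, gamma = NULL, epsilon = 0.1,
                        cost = 1) {
  correct_drift(pt, meta, min_qc, fit_fun = function(x, y) {
    if (stats::sd(y) == 0) return(function(newx) rep(y[1], length(newx)))
    args <- list(x = matrix(x, ncol = 1), y = y, type = "eps-regression",
                 kernel = "radial", epsilon = epsilon, cost = cost,
                 scale = TRUE)
    if (!is.null(gamma)) args$gamma <- gamma
    fit <- do.call(e1071::svm, args)
    function(newx) {
      as.numeric(stats::predict(
        fit, matrix(pmin(pmax(newx, min(x)), max(x)), ncol = 1)))
    }
  })
}

# Shared engine for QC-anchored drift correction in log space.
correct_drift <- function(pt, meta, min_qc, fit_fun) {
  meta <- align_meta(pt, meta)
  if (!any(meta$is_qc)) {
    stop("no QC samples: QC-based drift correction is impossible; ",
         "use sum/PQN/quantile or ComBat instead", call. = FALSE)
  }
  m <- intensity_matrix(pt)
  if (any(m <= 0, na.rm = TRUE)) {
    stop("drift correction requires positive intensities", call. = FALSE)
  }
  lg <- log(m)
  out <- lg
  batches <- split(seq_len(nrow(meta)), meta$batch)
  n_fallback <- 0L
  for (i in seq_len(nrow(lg))) {
    anchor <- stats::median(lg[i, meta$is_qc], na.rm = TRUE)
    if (!is.finite(anchor)) next  # no observed QC values: leave untouched
    for (cols in batches) {
      qc_cols <- cols[meta$is_qc[cols] & !is.na(lg[i, cols])]
      obs_cols <- cols[!is.na(lg[i, cols])]
      if (!length(obs_cols)) next
      if (length(qc_cols) >= min_qc) {
        drift <- fit_fun(meta$order[qc_cols], lg[i, qc_cols])
        out[i, obs_cols] <- lg[i, obs_cols] - drift(meta$order[obs_cols]) +
          anchor
      } else {
        n_fallback <- n_fallback + 1L
        batch_med <- if (length(qc_cols)) {
          stats::median(lg[i, qc_cols])
        } else anchor
        out[i, obs_cols] <- lg[i, obs_cols] - batch_med + anchor
      }
    }
  }
  if (n_fallback > 0) {
    message(n_fallback, " feature/batch combination(s) had < ", min_qc,
            " QC points; QC-median scaling fallback used")
  }
  set_intensities(pt, exp(out))
}
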