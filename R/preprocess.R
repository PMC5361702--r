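#' Filter features by detection rate
#'
#' A feature is removed when it is detected (observed, non-missing) in fewer
#' than `qc_frac` of the QC samples, or in fewer than `sample_frac` of the
#' experimental (non-QC) samples. With no QC samples present only the
#' experimental rule applies. The comparison is strict (`<`), so a feature
#' detected in exactly the threshold fraction is kept.
#'
#' @param pt A [peak_table()].
#' @param meta Sample metadata covering all samples (see [sample_meta()]).
#' @param qc_frac Minimum detected fraction among QC samples, in (0, 1].
#'   Default 0.5.
#' @param sample_frac Minimum detected fraction among experimental samples,
#'   in (0, 1]. Default 0.2.
#' @return The filtered [peak_table()].
#' @export
filter_features <- function(pt, meta, qc_frac = 0.5, sample_frac = 0.2) {
  stopifnot(qc_frac > 0, qc_frac <= 1, sample_frac > 0, sample_frac <= 1)
  meta <- align_meta(pt, meta)
  obs <- !is_missing(pt)
  qc <- meta$is_qc
  bad_sample <- if (any(!qc)) {
    rowMeans(obs[, !qc, drop = FALSE]) < sample_frac
  } else rep(FALSE, n_features(pt))
  bad_qc <- if (any(qc)) {
    rowMeans(obs[, qc, drop = FALSE]) < qc_frac
  } else rep(FALSE, n_features(pt))
  keep <- !(bad_qc | bad_sample)
  if (!any(keep)) warning("all features removed by detection-rate filter",
                          call. = FALSE)
  pt[keep, ]
}

#' Impute missing intensities
#'
#' @description
#' Replaces every missing cell with an estimate; observed values are never
#' altered.
#'
#' * `knn` — for each missing cell, the mean value (in that sample) of the
#'   `k` nearest features by Euclidean distance over co-observed samples.
#' * `svd` — iterative low-rank (rank `rank`) SVD reconstruction, initialised
#'   at feature means, iterated until the relative Frobenius change of the
#'   imputed matrix falls below `tol`.
#' * `rf` — iterative random-forest regression per feature with missing
#'   values (most-complete first), repeated until the change in imputed
#'   values stops decreasing (missForest-style stopping), seeded.
#' * `min_half` — half of the feature's observed minimum, a left-censoring
#'   surrogate for values below the detection limit.
#' * `bpca` — reserved; raises a not-implemented error.
#'
#' @param pt A [peak_table()].
#' @param method One of `"knn"`, `"svd"`, `"rf"`, `"min_half"`, `"bpca"`.
#' @param k Number of neighbour features for `knn`. Default 10.
#' @param rank Target rank for `svd`. Default 3.
#' @param tol Relative-change convergence tolerance for the iterative
#'   methods. Default 1e-6.
#' @param max_iter Iteration cap for `svd`/`rf`. Defaults 100 / 10.
#' @param seed Integer seed (used by `rf`).
#' @return A complete [peak_table()] (no missing cells).
#' @export
impute_missing <- function(pt, method = c("knn", "svd", "rf", "min_half", "bpca"),
                           k = 10, rank = 3, tol = 1e-6,
                           max_iter = if (method == "rf") 10 else 100,
                           seed = 1L) {
  method <- match.arg(method)
  if (method == "bpca") {
    stop("BPCA imputation is not implemented; use knn, svd, rf or min_half",
         call. = FALSE)
  }
  m <- intensity_matrix(pt)
  all_missing <- rownames(m)[rowSums(!is.na(m)) == 0]
  if (length(all_missing)) {
    stop("feature(s) with no observed values cannot be imputed: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  if (!anyNA(m)) return(pt)
  filled <- switch(method,
    knn = impute_knn(m, k),
    svd = impute_svd(m, rank, tol, max_iter),
    rf = impute_rf(m, tol, max_iter, seed),
    min_half = impute_min_half(m)
  )
  filled[!is.na(m)] <- m[!is.na(m)]  # observed cells are inviolate
  set_intensities(pt, filled)
}

impute_min_half <- function(m) {
  mins <- apply(m, 1, min, na.rm = TRUE)
  out <- m
  for (i in seq_len(nrow(m))) out[i, is.na(m[i, ])] <- mins[i] / 2
  out
}

impute_knn <- function(m, k) {
  out <- m
  fallback <- rowMeans(m, na.rm = TRUE)
  for (i in which(rowSums(is.na(m)) > 0)) {
    co <- !is.na(m[i, ])
    # squared distance over samples observed in both features, length-scaled
    d <- vapply(seq_len(nrow(m)), function(j) {
      both <- co & !is.na(m[j, ])
      if (j == i || !any(both)) return(Inf)
      mean((m[i, both] - m[j, both])^2)
    }, numeric(1))
    nn <- order(d)[seq_len(min(k, sum(is.finite(d))))]
    nn <- nn[is.finite(d[nn])]
    for (s in which(is.na(m[i, ]))) {
      vals <- m[nn, s]
      vals <- vals[!is.na(vals)]
      out[i, s] <- if (length(vals)) mean(vals) else fallback[i]
    }
  }
  out
}

impute_svd <- function(m, rank, tol, max_iter) {
  na <- is.na(m)
  x <- m
  x[na] <- rowMeans(m, na.rm = TRUE)[row(m)[na]]
  r <- min(rank, dim(m) - 1L)
  for (iter in seq_len(max_iter)) {
    mu <- rowMeans(x)
    s <- svd(x - mu, nu = r, nv = r)
    recon <- s$u %*% (diag(s$d[seq_len(r)], r, r) %*% t(s$v)) + mu
    delta <- sqrt(sum((recon[na] - x[na])^2)) / max(sqrt(sum(x[na]^2)), 1e-12)
    x[na] <- recon[na]
    if (delta < tol) break
  }
  x
}

impute_rf <- function(m, tol, max_iter, seed) {
  set.seed(seed)
  na <- is.na(m)                  # features x samples
  x <- t(impute_min_half(m))      # samples x features for regression
  target <- which(rowSums(na) > 0)
  target <- target[order(rowSums(na)[target])]  # most complete first
  prev_change <- Inf
  for (iter in seq_len(max_iter)) {
    old <- x
    for (j in target) {
      obs <- !na[j, ]
      fit <- suppressWarnings(randomForest::randomForest(
        x = x[obs, -j, drop = FALSE], y = x[obs, j],
        ntree = 100
      ))
      x[!obs, j] <- stats::predict(fit, x[!obs, -j, drop = FALSE])
    }
    change <- sum((x - old)^2) / max(sum(x^2), 1e-12)
    if (change >= prev_change || change < tol) break
    prev_change <- change
  }
  t(x)
}

#' Transform intensities
#'
#' Elementwise variance-stabilising transforms:
#' * `log` — `log_base(x + offset)`; requires all values (plus offset)
#'   positive.
#' * `glog` — generalised logarithm
#'   `log_base((x + sqrt(x^2 + lambda)) / 2)`; `lambda = NULL` (auto) uses the
#'   square of the smallest positive observed intensity.
#' * `cube_root` — sign-preserving `sign(x) * |x|^(1/3)`.
#'
#' @param pt A [peak_table()].
#' @param method `"log"`, `"glog"` or `"cube_root"`.
#' @param base Logarithm base. Default 2.
#' @param lambda glog softening constant; `NULL` for auto.
#' @param offset Additive offset for `log`. Default 0.
#' @return The transformed [peak_table()].
#' @export
transform_intensities <- function(pt, method = c("log", "glog", "cube_root"),
                                  base = 2, lambda = NULL, offset = 0) {
  method <- match.arg(method)
  m <- intensity_matrix(pt)
  out <- switch(method,
    log = {
      if (any(m + offset <= 0, na.rm = TRUE)) {
        stop("log transform requires positive values; set `offset` or use glog",
             call. = FALSE)
      }
      log(m + offset, base = base)
    },
    glog = {
      if (is.null(lambda)) {
        pos <- m[!is.na(m) & m > 0]
        if (!length(pos)) stop("no positive values to set glog lambda",
                               call. = FALSE)
        lambda <- min(pos)^2
      }
      log((m + sqrt(m^2 + lambda)) / 2, base = base)
    },
    cube_root = sign(m) * abs(m)^(1 / 3)
  )
  set_intensities(pt, out)
}

#' Scale features
#'
#' Feature-wise (row-wise) scaling. With per-feature mean `m`, sample
#' standard deviation `s` (n-1 denominator) and range `r`:
#' auto `(x-m)/s`; pareto `(x-m)/sqrt(s)`; range `(x-m)/r`;
#' vast `((x-m)/s) * (m/s)`; level `(x-m)/m`; center `x-m`; none `x`.
#'
#' Features whose required denominator (`s`, `r` or `m`) is zero are dropped
#' with a warning, or raise an error with `on_degenerate = "error"`.
#'
#' @param pt A [peak_table()].
#' @param method Scaling method.
#' @param on_degenerate `"drop"` (default) or `"error"`.
#' @return The scaled [peak_table()].
#' @export
scale_features <- function(pt, method = c("auto", "pareto", "range", "vast",
                                          "level", "center", "none"),
                           on_degenerate = c("drop", "error")) {
  method <- match.arg(method)
  on_degenerate <- match.arg(on_degenerate)
  if (method == "none") return(pt)
  m <- intensity_matrix(pt)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, stats::sd, na.rm = TRUE)
  r <- apply(m, 1, function(x) diff(range(x, na.rm = TRUE)))
  denom <- switch(method,
    auto = s, pareto = sqrt(s), vast = s, range = r, level = mu,
    center = rep(1, nrow(m)))
  bad <- !is.na(denom) & denom == 0
  if (method %in% c("auto", "pareto", "vast")) bad <- bad | is.na(s)
  if (any(bad)) {
    msg <- paste0(sum(bad), " feature(s) with zero ",
                  switch(method, range = "range", level = "mean", "sd"),
                  " cannot be ", method, "-scaled")
    if (on_degenerate == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    m <- m[!bad, , drop = FALSE]
    mu <- mu[!bad]; s <- s[!bad]; denom <- denom[!bad]
  }
  centred <- m - mu
  out <- switch(method,
    center = centred,
    vast = (centred / s) * (mu / s),
    centred / denom
  )
  set_intensities(pt, out)
}

#' PCA-ellipse outlier removal
#'
#' Iteratively removes samples falling outside the Hotelling T-squared
#' ellipse of a two-component PCA score plot. Each round fits PCA on the
#' current samples; sample i is an outlier when
#' `T2_i = t1_i^2/s1^2 + t2_i^2/s2^2` exceeds
#' `expand^2 * 2(n-1)/(n-2) * qf(conf, 2, n-2)`. Outliers are removed, the
#' model refit, and the process repeated up to `max_rounds` rounds, stopping
#' early when a round removes nothing or fewer than 4 samples would remain.
#'
#' The input is used as-is: apply any transformation/scaling first.
#'
#' @param pt A [peak_table()] with no missing values (impute first).
#' @param meta Sample metadata (carried through; not used to fit).
#' @param max_rounds Maximum removal rounds. Default 3.
#' @param conf Ellipse confidence level. Default 0.95.
#' @param expand Ellipse expansion factor (> 1 is more permissive).
#'   Default 1.
#' @return An `outlier_result` list: `final_table` (the cleaned
#'   [peak_table()]), `removed` (tibble round/sample/t2), `rounds_run`,
#'   and the per-round T2 threshold.
#' @export
remove_outliers <- function(pt, meta = NULL, max_rounds = 3, conf = 0.95,
                            expand = 1.0) {
  if (anyNA(intensity_matrix(pt))) {
    stop("remove_outliers requires a complete table; impute first", call. = FALSE)
  }
  if (n_samples(pt) < 4) stop("need at least 4 samples", call. = FALSE)
  removed <- tibble::tibble(round = integer(), sample = character(),
                            t2 = numeric())
  cur <- pt
  rounds_run <- 0L
  thresholds <- numeric()
  for (round in seq_len(max_rounds)) {
    n <- n_samples(cur)
    if (n < 4) {
      warning("fewer than 4 samples remain; stopping outlier removal",
              call. = FALSE)
      break
    }
    rounds_run <- round
    sc <- stats::prcomp(t(intensity_matrix(cur)), center = TRUE,
                        scale. = FALSE)
    t1 <- sc$x[, 1]
    t2c <- if (ncol(sc$x) >= 2) sc$x[, 2] else rep(0, n)
    s1 <- stats::sd(t1)
    s2 <- stats::sd(t2c)
    tsq <- t1^2 / s1^2 + if (s2 > 0) t2c^2 / s2^2 else 0
    lim <- expand^2 * 2 * (n - 1) / (n - 2) * stats::qf(conf, 2, n - 2)
    thresholds <- c(thresholds, lim)
    out <- which(tsq > lim)
    if (length(out) == 0L) break
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      round = round, sample = sample_ids(cur)[out], t2 = unname(tsq[out])))
    cur <- cur[, -out]
  }
  structure(list(final_table = cur, removed = removed,
                 rounds_run = rounds_run, t2_threshold = thresholds,
                 conf = conf, expand = expand),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("<outlier_result> ", nrow(x$removed), " sample(s) removed in ",
      x$rounds_run, " round(s)\n", sep = "")
  if (nrow(x$removed)) print(x$removed)
  invisible(x)
}

#' @export
tidy.outlier_result <- function(x, ...) x$removed

#' @export
glance.outlier_result <- function(x, ...) {
  tibble::tibble(n_removed = nrow(x$removed), rounds_run = x$rounds_run,
                 n_samples_final = n_samples(x$final_table),
                 conf = x$conf, expand = x$expand)
}
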