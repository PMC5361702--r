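#' Principal component analysis of a peak table
#'
#' Samples are observations, features are variables; scores and loadings
#' come from the singular-value decomposition of the (column-centred)
#' sample x feature matrix. Apply any transformation/scaling beforehand.
#'
#' @param pt A complete [peak_table()] (no missing values).
#' @param n_components Number of components to keep. Default 2.
#' @param center Centre features before decomposition. Default `TRUE`.
#' @return A `multivariate_model` with `kind = "pca"`, `scores`
#'   (samples x components), `loadings` (features x components) and
#'   `explained_variance` fractions.
#' @export
pca_fit <- function(pt, n_components = 2, center = TRUE) {
  m <- t(intensity_matrix(pt))
  if (anyNA(m)) stop("PCA requires a complete table; impute first", call. = FALSE)
  if (n_components > min(dim(m))) {
    stop("n_components exceeds min(n_samples, n_features)", call. = FALSE)
  }
  fit <- stats::prcomp(m, center = center, scale. = FALSE)
  k <- seq_len(n_components)
  structure(list(
    kind = "pca",
    scores = fit$x[, k, drop = FALSE],
    loadings = fit$rotation[, k, drop = FALSE],
    explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[k],
    n_components = n_components
  ), class = "multivariate_model")
}

# Extract the sample x feature matrix and a -1/+1 response for a two-group
# comparison; QCs and unrelated classes are dropped.
xy_for_groups <- function(pt, meta, case = NULL, control = NULL) {
  meta <- align_meta(pt, meta)
  classes <- sort(unique(stats::na.omit(meta$class)))
  if (is.null(case) || is.null(control)) {
    if (length(classes) != 2) {
      stop("exactly two experimental groups required (got ",
           length(classes), "); specify case/control", call. = FALSE)
    }
    case <- classes[1]; control <- classes[2]
  }
  sel <- !is.na(meta$class) & meta$class %in% c(case, control)
  x <- t(intensity_matrix(pt)[, sel, drop = FALSE])
  if (anyNA(x)) stop("PLS requires a complete table; impute first", call. = FALSE)
  y <- ifelse(meta$class[sel] == case, 1, -1)
  list(x = x, y = y, case = case, control = control,
       labels = meta$class[sel])
}

# Single NIPALS PLS1 fit on centred data. Returns weights (normalized),
# scores, loadings, per-component explained-Y sums of squares, and the
# regression vector for prediction.
pls1_core <- function(x, y, ncomp) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  p <- ncol(x)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(x), ncomp); qv <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xd <- xc; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - q_ * t_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; qv[a] <- q_
    ssy[a] <- q_^2 * tt
  }
  k <- seq_len(ncomp)
  W <- W[, k, drop = FALSE]; P <- P[, k, drop = FALSE]
  Tm <- Tm[, k, drop = FALSE]; qv <- qv[k]; ssy <- ssy[k]
  beta <- W %*% solve(t(P) %*% W, qv)
  fitted <- mean(y) + scale(x, center = colMeans(x), scale = FALSE) %*% beta
  list(weights = W, loadings = P, scores = Tm, q = qv, ssy = ssy,
       beta = beta, x_means = colMeans(x), y_mean = mean(y),
       fitted = as.numeric(fitted), ncomp = ncomp)
}

pls1_predict <- function(fit, newx) {
  as.numeric(sweep(newx, 2, fit$x_means) %*% fit$beta + fit$y_mean)
}

pls_vip <- function(fit) {
  p <- nrow(fit$weights)
  ssy <- fit$ssy
  vip <- sqrt(p * as.numeric(fit$weights^2 %*% ssy) / sum(ssy))
  vip
}

# Stratified fold assignment: samples of each class are dealt round-robin
# over folds after a seeded shuffle.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Partial least squares discriminant analysis (PLS-DA)
#'
#' Two-group PLS-DA with a -1/+1 dummy response, fitted by NIPALS.
#' R2Y is the fraction of response variance captured by the fitted values;
#' Q2Y is the corresponding cross-validated quantity from seeded stratified
#' k-fold prediction; VIP is
#' `sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` so mean squared VIP is 1.
#'
#' @param pt A complete [peak_table()] (transform/scale first; the usual
#'   preset is glog + Pareto).
#' @param meta [sample_meta()].
#' @param case,control Group labels; default: the only two classes present.
#' @param n_components Number of PLS components. Default 2.
#' @param cv_folds Cross-validation folds for Q2Y. Default 7.
#' @param seed Seed for the fold split.
#' @return A `multivariate_model` with `kind = "plsda"`, scores, loadings,
#'   weights, `r2y`, `q2y`, `vip`.
#' @export
plsda_fit <- function(pt, meta, case = NULL, control = NULL,
                      n_components = 2, cv_folds = 7, seed = 1L) {
  d <- xy_for_groups(pt, meta, case, control)
  n_components <- min(n_components, ncol(d$x), nrow(d$x) - 1L)
  fit <- pls1_core(d$x, d$y, n_components)
  sstot <- sum((d$y - mean(d$y))^2)
  r2y <- 1 - sum((d$y - fit$fitted)^2) / sstot
  q2y <- pls_q2(d$x, d$y, n_components, cv_folds, seed,
                fitter = pls1_core, predictor = pls1_predict)
  structure(list(
    kind = "plsda", scores = fit$scores, loadings = fit$loadings,
    weights = fit$weights, r2y = r2y, q2y = q2y,
    vip = stats::setNames(pls_vip(fit), colnames(d$x)),
    n_components = fit$ncomp, n_orthogonal = 0L,
    case = d$case, control = d$control,
    response = d$y, sample_ids = rownames(d$x)
  ), class = "multivariate_model")
}

pls_q2 <- function(x, y, ncomp, cv_folds, seed, fitter, predictor, ...) {
  k <- max(2, min(cv_folds, min(table(y)), nrow(x) - 1))
  fold <- stratified_folds(y, k, seed)
  press <- 0
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    fit_f <- fitter(x[tr, , drop = FALSE], y[tr], ncomp, ...)
    pred <- predictor(fit_f, x[te, , drop = FALSE])
    press <- press + sum((y[te] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

# O-PLS: strip n_orth orthogonal components, then fit 1 predictive PLS
# component on the filtered matrix (Trygg & Wold deflation).
opls_core <- function(x, y, n_orth) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  x_means <- colMeans(x)
  yc <- y - mean(y)
  w <- crossprod(xc, yc); w <- w / sqrt(sum(w^2))
  Wo <- NULL; Po <- NULL; To <- NULL
  Xd <- xc
  for (a in seq_len(n_orth)) {
    t_ <- Xd %*% w
    p_ <- crossprod(Xd, t_) / sum(t_^2)
    w_o <- p_ - as.numeric(crossprod(w, p_)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    Wo <- cbind(Wo, w_o); Po <- cbind(Po, p_o); To <- cbind(To, t_o)
  }
  # predictive component on the orthogonality-filtered matrix
  wp <- crossprod(Xd, yc); wp <- wp / sqrt(sum(wp^2))
  tp <- Xd %*% wp
  pp <- crossprod(Xd, tp) / sum(tp^2)
  qp <- sum(yc * tp) / sum(tp^2)
  fitted <- mean(y) + qp * tp
  list(w_pred = wp, t_pred = tp, p_pred = pp, q_pred = qp,
       w_orth = Wo, p_orth = Po, t_orth = To,
       x_means = x_means, y_mean = mean(y),
       fitted = as.numeric(fitted), ssy = qp^2 * sum(tp^2),
       n_orth = if (is.null(To)) 0L else ncol(To))
}

opls_predict <- function(fit, newx) {
  xc <- sweep(newx, 2, fit$x_means)
  if (fit$n_orth > 0) {
    for (a in seq_len(fit$n_orth)) {
      t_o <- xc %*% fit$w_orth[, a]
      xc <- xc - t_o %*% t(fit$p_orth[, a])
    }
  }
  tp <- xc %*% fit$w_pred
  as.numeric(fit$y_mean + fit$q_pred * tp)
}

#' Orthogonal PLS discriminant analysis (OPLS-DA)
#'
#' One predictive component plus `n_orthogonal` orthogonal components
#' removed by the O-PLS deflation scheme; with one of each this is the
#' usual two-component model. R2Y/Q2Y as in [plsda_fit()]; VIP is computed
#' from the predictive component.
#'
#' @inheritParams plsda_fit
#' @param n_orthogonal Number of orthogonal components. Default 1.
#' @return A `multivariate_model` with `kind = "oplsda"`; `scores` has the
#'   predictive score in column 1 and orthogonal scores after it.
#' @export
oplsda_fit <- function(pt, meta, case = NULL, control = NULL,
                       n_orthogonal = 1, cv_folds = 7, seed = 1L) {
  d <- xy_for_groups(pt, meta, case, control)
  fit <- opls_core(d$x, d$y, n_orthogonal)
  sstot <- sum((d$y - mean(d$y))^2)
  r2y <- 1 - sum((d$y - fit$fitted)^2) / sstot
  q2y <- pls_q2(d$x, d$y, n_orthogonal, cv_folds, seed,
                fitter = opls_core, predictor = opls_predict)
  p <- ncol(d$x)
  vip <- sqrt(p * as.numeric(fit$w_pred^2))  # single predictive component
  scores <- cbind(pred = fit$t_pred, fit$t_orth)
  colnames(scores) <- c("pred", if (fit$n_orth > 0)
    paste0("orth", seq_len(fit$n_orth)))
  rownames(scores) <- rownames(d$x)
  structure(list(
    kind = "oplsda", scores = scores,
    loadings = cbind(pred = fit$p_pred, fit$p_orth),
    weights = cbind(pred = fit$w_pred, fit$w_orth),
    r2y = r2y, q2y = q2y, vip = stats::setNames(vip, colnames(d$x)),
    n_components = 1L + fit$n_orth, n_orthogonal = fit$n_orth,
    case = d$case, control = d$control,
    response = d$y, sample_ids = rownames(d$x)
  ), class = "multivariate_model")
}

#' Permutation test of a PLS-DA / OPLS-DA model
#'
#' Refits the model `n_perm` times with the class labels permuted and
#' reports `p = (1 + #\{Q2Y_perm >= Q2Y_obs\}) / (1 + n_perm)`.
#'
#' @param pt A complete [peak_table()].
#' @param meta [sample_meta()].
#' @param model_kind `"plsda"` or `"oplsda"`.
#' @param n_perm Number of permutations. Default 200.
#' @param seed Seed for both the CV splits and the permutations.
#' @param ... Passed to the model fitter (e.g. `n_components`, `cv_folds`).
#' @return A `permutation_result` list: `p_value`, `q2y_observed`,
#'   `q2y_permuted` (vector), `n_perm`.
#' @export
permutation_test <- function(pt, meta, model_kind = c("plsda", "oplsda"),
                             n_perm = 200, seed = 1L, ...) {
  model_kind <- match.arg(model_kind)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  fitter <- if (model_kind == "plsda") plsda_fit else oplsda_fit
  obs <- fitter(pt, meta, seed = seed, ...)
  meta_al <- align_meta(pt, meta)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_perm)
  q2_perm <- vapply(seq_len(n_perm), function(i) {
    pm <- meta_al
    lab <- pm$class[!pm$is_qc]
    pm$class[!pm$is_qc] <- sample(lab)
    fitter(pt, pm, seed = seeds[i], ...)$q2y
  }, numeric(1))
  structure(list(
    p_value = (1 + sum(q2_perm >= obs$q2y)) / (1 + n_perm),
    q2y_observed = obs$q2y, q2y_permuted = q2_perm, n_perm = n_perm,
    model_kind = model_kind
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$model_kind, ": observed Q2Y = ",
      round(x$q2y_observed, 4), ", p = ", signif(x$p_value, 3),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
print.multivariate_model <- function(x, ...) {
  cat("<multivariate_model> ", x$kind, ", ", x$n_components, " component(s)",
      sep = "")
  if (!is.null(x$r2y)) cat("; R2Y = ", round(x$r2y, 3),
                           ", Q2Y = ", round(x$q2y, 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy scores of a multivariate model
#'
#' @param x A `multivariate_model`.
#' @param ... Unused.
#' @return A tibble of per-sample scores (one column per component).
#' @export
tidy.multivariate_model <- function(x, ...) {
  sc <- tibble::as_tibble(x$scores, rownames = "sample",
                          .name_repair = "unique")
  if (!is.null(x$response)) {
    sc$group <- ifelse(x$response > 0, x$case, x$control)
  }
  sc
}

#' One-row summary of a multivariate model
#'
#' @param x A `multivariate_model`.
#' @param ... Unused.
#' @export
glance.multivariate_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_components = x$n_components,
    n_orthogonal = x$n_orthogonal %||% NA_integer_,
    r2y = x$r2y %||% NA_real_,
    q2y = x$q2y %||% NA_real_,
    explained_variance_1 = if (!is.null(x$explained_variance))
      x$explained_variance[1] else NA_real_
  )
}
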