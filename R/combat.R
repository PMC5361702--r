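#' Empirical-Bayes batch correction
#'
#' Location/scale batch adjustment of log-intensities in the ComBat style:
#' per feature, fit grand mean and per-batch deviations; standardize; then
#' shrink each batch's per-feature location (`gamma`) and scale (`delta^2`)
#' estimates toward batch-level parametric priors — normal for `gamma`,
#' inverse-gamma for `delta^2` — via the standard iterative EB update;
#' adjust and back-transform to the intensity scale. Missing cells are
#' ignored in every estimate and stay missing.
#'
#' @param pt A [peak_table()] of positive intensities.
#' @param meta [sample_meta()] with batch labels.
#' @param parametric Use parametric priors (the only mode implemented;
#'   kept as an argument for interface stability). Default `TRUE`.
#' @param tol,max_iter Convergence control for the EB fixed-point iteration.
#' @return The corrected [peak_table()].
#' @export
combat_correct <- function(pt, meta, parametric = TRUE, tol = 1e-8,
                           max_iter = 200) {
  if (!parametric) stop("only the parametric EB adjustment is implemented",
                        call. = FALSE)
  meta <- align_meta(pt, meta)
  batch <- factor(meta$batch)
  if (nlevels(batch) < 2) {
    warning("single batch: nothing to correct", call. = FALSE)
    return(pt)
  }
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples", call. = FALSE)
  m <- intensity_matrix(pt)
  if (any(m <= 0, na.rm = TRUE)) {
    stop("batch correction requires positive intensities", call. = FALSE)
  }
  lg <- log(m)
  b_idx <- lapply(levels(batch), function(b) which(batch == b))
  for (cols in b_idx) {
    if (any(rowSums(!is.na(lg[, cols, drop = FALSE])) == 0)) {
      stop("feature(s) entirely missing within a batch", call. = FALSE)
    }
  }
  nb <- length(b_idx)
  p <- nrow(lg)

  # per-feature grand mean (batch-size weighted) and pooled variance
  batch_means <- vapply(b_idx, function(cols)
    rowMeans(lg[, cols, drop = FALSE], na.rm = TRUE), numeric(p))
  n_per <- vapply(b_idx, function(cols)
    rowSums(!is.na(lg[, cols, drop = FALSE])), numeric(p))
  grand <- rowSums(batch_means * n_per) / rowSums(n_per)
  resid <- lg - grand
  pooled_var <- rowSums(resid^2, na.rm = TRUE) / rowSums(!is.na(lg))
  pooled_var[pooled_var == 0] <- 1e-12
  z <- resid / sqrt(pooled_var)

  adj <- z
  for (k in seq_len(nb)) {
    cols <- b_idx[[k]]
    zk <- z[, cols, drop = FALSE]
    gamma_hat <- rowMeans(zk, na.rm = TRUE)
    nk <- rowSums(!is.na(zk))
    delta_hat <- rowSums((zk - gamma_hat)^2, na.rm = TRUE) / pmax(nk - 1, 1)
    delta_hat[delta_hat == 0 | !is.finite(delta_hat)] <- 1e-12

    # parametric priors across features
    g_bar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    if (!is.finite(t2) || t2 == 0) t2 <- 1e-12
    a_prior <- ig_a(delta_hat)
    b_prior <- ig_b(delta_hat)

    g_star <- gamma_hat
    d_star <- delta_hat
    for (iter in seq_len(max_iter)) {
      g_new <- (t2 * nk * gamma_hat + d_star * g_bar) / (t2 * nk + d_star)
      ssq <- rowSums(sweep(zk, 1, g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * ssq + b_prior) / (nk / 2 + a_prior - 1)
      change <- max(abs(g_new - g_star) / (abs(g_star) + 1e-12),
                    abs(d_new - d_star) / (abs(d_star) + 1e-12))
      g_star <- g_new; d_star <- d_new
      if (change < tol) break
    }
    adj[, cols] <- (zk - g_star) / sqrt(d_star)
  }

  out <- adj * sqrt(pooled_var) + grand
  set_intensities(pt, exp(out))
}

# Method-of-moments inverse-gamma hyperparameters (ComBat conventions).
ig_a <- function(d) {
  m <- mean(d); v <- stats::var(d)
  if (!is.finite(v) || v == 0) v <- 1e-12
  (2 * v + m^2) / v
}
ig_b <- function(d) {
  m <- mean(d); v <- stats::var(d)
  if (!is.finite(v) || v == 0) v <- 1e-12
  (m * v + m^3) / v
}
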