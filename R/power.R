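#' Power / sample-size curve from pilot statistics
#'
#' A light-weight power projection from a pilot two-group comparison.
#' The fraction of null features `pi0` is estimated by the Storey median
#' estimator (`pi0 = min(1, #\{p > 0.5\} / (m / 2))`); the
#' `(1 - pi0) * m` largest absolute t-statistics are converted to
#' standardized effect sizes `d = t * sqrt(1/n1 + 1/n2)`; for each
#' candidate per-group sample size the average two-sided two-sample t-test
#' power over that effect-size set is computed from the noncentral t
#' distribution (via [stats::power.t.test()]). When no non-null effects are
#' estimated the curve is flat at `alpha`.
#'
#' @param statistics Per-feature t-statistics from the pilot comparison.
#' @param n1,n2 Pilot per-group sample sizes.
#' @param n_grid Candidate per-group sample sizes (positive integers).
#' @param alpha Two-sided significance level. Default 0.05.
#' @return A `power_curve` tibble with columns `n_per_group` and
#'   `estimated_power`, and attributes `alpha` and `pi0`.
#' @export
estimate_power <- function(statistics, n1, n2, n_grid, alpha = 0.05) {
  if (length(n_grid) == 0) stop("`n_grid` must be non-empty", call. = FALSE)
  stopifnot(all(n_grid >= 2), n1 >= 2, n2 >= 2)
  statistics <- statistics[!is.na(statistics)]
  m <- length(statistics)
  if (m == 0) stop("no pilot statistics supplied", call. = FALSE)
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(statistics), df = df)
  pi0 <- min(1, sum(p > 0.5) / (m / 2))
  m1 <- round(m * (1 - pi0))
  effects <- if (m1 > 0) {
    d <- abs(statistics) * sqrt(1 / n1 + 1 / n2)
    sort(d, decreasing = TRUE)[seq_len(m1)]
  } else numeric(0)
  power <- vapply(n_grid, function(n) {
    if (length(effects) == 0) return(alpha)
    mean(vapply(effects, function(d) {
      stats::power.t.test(n = n, delta = d, sd = 1, sig.level = alpha,
                          type = "two.sample",
                          alternative = "two.sided")$power
    }, numeric(1)))
  }, numeric(1))
  out <- tibble::tibble(n_per_group = as.integer(n_grid),
                        estimated_power = power)
  attr(out, "alpha") <- alpha
  attr(out, "pi0") <- pi0
  class(out) <- c("power_curve", class(out))
  out
}
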