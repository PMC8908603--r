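#' Paired measurements of one metric
#'
#' Container for scan/rescan (or read/re-read) pairs of a single LV metric.
#'
#' @param x1,x2 paired measurements (equal length >= 2, finite).
#' @param subject optional subject identifiers.
#' @return object of class `paired_measurements`.
#' @export
paired_measurements <- function(x1, x2, subject = seq_along(x1)) {
  if (length(x1) != length(x2) || length(x1) < 2L)
    cmr_stop("data_error", "need >= 2 pairs of equal length")
  if (any(!is.finite(x1)) || any(!is.finite(x2)))
    cmr_stop("data_error", "non-finite measurement")
  structure(list(subject = subject, x1 = as.numeric(x1),
                 x2 = as.numeric(x2)),
            class = "paired_measurements")
}

#' Within-subject coefficient of variation (root-mean-squared method)
#'
#' The standard error of measurement (SEM, the within-subject standard
#' deviation) is computed by the root-mean-squared method,
#' `sem = sqrt(sum(d_i^2) / (2n))` with `d_i = x1_i - x2_i`, and the CoV is
#' `100 * sem / grand mean` over all `2n` measurements. This equals the
#' square root of the residual mean square of a one-way subject-factor
#' ANOVA on the same data.
#'
#' @param pairs a [paired_measurements] (or a list with `x1`, `x2`).
#' @param denominator `"grand_mean"` (default) or `"pair_means"` (mean of
#'   per-pair means — identical for balanced pairs, offered for sensitivity
#'   analysis).
#' @return list with `cov_pct` and `sem`.
#' @export
cov_within_subject <- function(pairs, denominator = c("grand_mean",
                                                      "pair_means")) {
  denominator <- match.arg(denominator)
  d <- pairs$x1 - pairs$x2
  n <- length(d)
  if (n < 2L) cmr_stop("data_error", "need >= 2 pairs")
  sem <- sqrt(sum(d^2) / (2 * n))
  xbar <- if (denominator == "grand_mean") mean(c(pairs$x1, pairs$x2))
  else mean((pairs$x1 + pairs$x2) / 2)
  if (xbar == 0) cmr_stop("data_error", "grand mean is zero; CoV undefined")
  list(cov_pct = 100 * sem / xbar, sem = sem)
}

#' Bootstrap confidence interval for a paired statistic
#'
#' Resamples subjects with replacement (pairs kept intact), recomputes the
#' statistic on each resample, and returns the percentile interval. Used
#' with `n_boot = 10000` to attach standard errors and confidence intervals
#' to within-subject CoV estimates.
#'
#' @param pairs a [paired_measurements].
#' @param statistic function of a `paired_measurements` returning one number.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed (bit-reproducible given the seed).
#' @param level confidence level.
#' @param type `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with jackknife acceleration).
#' @return list with `estimate`, `se`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_ci <- function(pairs, statistic, n_boot = 10000L, seed = 1L,
                         level = 0.95, type = c("percentile", "bca")) {
  type <- match.arg(type)
  n <- length(pairs$x1)
  if (n < 2L) cmr_stop("data_error", "need >= 2 pairs")
  est <- statistic(pairs)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  resample <- function(i) list(subject = pairs$subject[i], x1 = pairs$x1[i],
                               x2 = pairs$x2[i])
  stats_b <- vapply(seq_len(n_boot), function(b) statistic(resample(idx[b, ])),
                    numeric(1))
  alpha <- (1 - level) / 2
  probs <- c(alpha, 1 - alpha)
  if (type == "bca") {
    z0 <- stats::qnorm(pmin(pmax(mean(stats_b < est), 1 / n_boot),
                            1 - 1 / n_boot))
    jack <- vapply(seq_len(n), function(i) statistic(resample(seq_len(n)[-i])),
                   numeric(1))
    jm <- mean(jack)
    denom <- 6 * sum((jm - jack)^2)^1.5
    a <- if (denom == 0) 0 else sum((jm - jack)^3) / denom
    zq <- stats::qnorm(probs)
    probs <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  }
  qs <- stats::quantile(stats_b, probs, names = FALSE, type = 7)
  list(estimate = est, se = stats::sd(stats_b),
       ci_low = qs[1L], ci_high = qs[2L], n_boot = n_boot)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two sets of measurements, penalising both loss of
#' correlation and location/scale shift:
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return value in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    cmr_stop("data_error", "need equal-length vectors, n >= 2")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  if (vx == 0 || vy == 0)
    cmr_stop("data_error", "zero variance; CCC undefined")
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (vx + vy + (mx - my)^2)
}

#' Bland-Altman bias and limits of agreement
#'
#' @param x,y paired measurements.
#' @return list with `bias` (mean difference) and `loa_low`/`loa_high`
#'   (bias -/+ 1.96 sample standard deviations of the differences).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    cmr_stop("data_error", "need equal-length vectors, n >= 2")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Minimal detectable change
#'
#' The smallest between-scan change distinguishable from measurement noise
#' at 95% confidence: `1.96 * sqrt(2) * SEM`.
#'
#' @param sem standard error of measurement (within-subject SD), any units.
#' @return MDC in the same units.
#' @export
minimal_detectable_change <- function(sem) {
  if (any(sem < 0)) cmr_stop("domain_error", "sem must be non-negative")
  1.96 * sqrt(2) * sem
}

#' Sample size per group for a standardized difference
#'
#' Normal-approximation two-group sample size:
#' `n = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 / delta^2)` per group.
#'
#' @param standardized_difference effect size delta (> 0).
#' @param power target power (default 0.9).
#' @param alpha significance level (default 0.05).
#' @param two_sided two-sided test (default TRUE).
#' @return integer sample size per group.
#' @export
sample_size_per_group <- function(standardized_difference, power = 0.9,
                                  alpha = 0.05, two_sided = TRUE) {
  if (standardized_difference <= 0)
    cmr_stop("domain_error", "standardized difference must be positive")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    cmr_stop("domain_error", "power and alpha must lie in (0, 1)")
  za <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  zb <- stats::qnorm(power)
  max(1L, as.integer(ceiling(2 * (za + zb)^2 / standardized_difference^2)))
}

#' Relative sample-size reduction between two measurement methods
#'
#' For a trial powered to detect an absolute change `effect` in a metric,
#' the standardized difference under a scan-rescan design is
#' `delta = effect / (sqrt(2) * sem)` for each method; the reduction is
#' `100 * (1 - n_b / n_a)` percent. A more precise method (smaller SEM)
#' requires fewer subjects, following an inverse-variance law before the
#' integer ceiling.
#'
#' @param sem_a,sem_b standard errors of measurement of methods A and B.
#' @param effect absolute change to detect, same units (> 0).
#' @param power,alpha as in [sample_size_per_group].
#' @return percent reduction in required sample size of B relative to A.
#' @export
sample_size_reduction <- function(sem_a, sem_b, effect, power = 0.9,
                                  alpha = 0.05) {
  if (effect <= 0) cmr_stop("domain_error", "effect must be positive")
  if (sem_a <= 0 || sem_b <= 0)
    cmr_stop("domain_error", "sem must be positive")
  na <- sample_size_per_group(effect / (sqrt(2) * sem_a), power, alpha)
  nb <- sample_size_per_group(effect / (sqrt(2) * sem_b), power, alpha)
  100 * (1 - nb / na)
}

#' Full precision report for one metric
#'
#' Bundles the scan-rescan precision statistics for one LV metric: CoV (with
#' bootstrap CI), SEM, MDC, Lin's CCC, Bland-Altman bias and limits of
#' agreement, and mean absolute difference.
#'
#' @param pairs a [paired_measurements].
#' @param metric metric name (for printing).
#' @param n_boot,seed,level bootstrap settings (see [bootstrap_ci]).
#' @return object of class `precision_report`.
#' @export
precision_report <- function(pairs, metric = "metric", n_boot = 10000L,
                             seed = 1L, level = 0.95) {
  cv <- cov_within_subject(pairs)
  boot <- bootstrap_ci(pairs, function(p) cov_within_subject(p)$cov_pct,
                       n_boot = n_boot, seed = seed, level = level)
  structure(list(
    metric = metric,
    cov_pct = cv$cov_pct, sem = cv$sem,
    cov_ci_low = boot$ci_low, cov_ci_high = boot$ci_high,
    cov_se = boot$se,
    mdc = minimal_detectable_change(cv$sem),
    ccc = tryCatch(ccc(pairs$x1, pairs$x2), cmrlv_error = function(e) NA_real_),
    bland_altman = bland_altman(pairs$x1, pairs$x2),
    mean_abs_diff = mean(abs(pairs$x1 - pairs$x2)),
    n_subjects = length(pairs$x1), n_boot = n_boot, seed = seed
  ), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("%s: CoV %.1f%% (%.1f-%.1f), SEM %.3g, MDC %.3g, CCC %.3f\n",
              x$metric, x$cov_pct, x$cov_ci_low, x$cov_ci_high, x$sem,
              x$mdc, x$ccc))
  cat(sprintf("  Bland-Altman bias %.3g (LoA %.3g to %.3g), MAD %.3g, n=%d\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high, x$mean_abs_diff, x$n_subjects))
  invisible(x)
}
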