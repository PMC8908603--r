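# Independent oracles used by several test files.

unitize_test <- function(v) v / sqrt(sum(v^2))

cross_prod_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Monte-Carlo sub-voxel clipping oracle for slice_volume: sample points
# uniformly inside every labelled pixel's slab column and count the fraction
# on the ventricular side of the plane. Sub-voxel offsets are shared across
# columns (a randomised quadrature of the whole slab).
mc_clip_oracle <- function(mask, plane, mv, label = 1L, n_samples = 1e5,
                           seed = 1L) {
  idx <- which(mask == label, arr.ind = TRUE)
  centres <- pixel_to_patient(plane, idx[, 1L] - 1, idx[, 2L] - 1)
  d0 <- mv_signed_distance(mv, centres)
  set.seed(seed)
  u <- runif(n_samples, -0.5, 0.5)
  v <- runif(n_samples, -0.5, 0.5)
  w <- runif(n_samples, -0.5, 0.5)
  e <- u * plane$row_spacing * sum(mv$normal * plane$row_dir) +
    v * plane$col_spacing * sum(mv$normal * plane$col_dir) +
    w * plane$slab_thickness * sum(mv$normal * plane_normal(plane))
  frac <- vapply(d0, function(d) mean(d + e > 0), numeric(1))
  sum(frac) * plane$row_spacing * plane$col_spacing *
    plane$slab_thickness / 1000
}

# One-way subject-factor ANOVA oracle for the within-subject SD: the
# residual mean square of value ~ subject equals sum(d^2) / (2n) for paired
# data.
anova_sem_oracle <- function(x1, x2) {
  n <- length(x1)
  df <- data.frame(value = c(x1, x2),
                   subject = factor(rep(seq_len(n), 2L)))
  fit <- stats::lm(value ~ subject, data = df)
  sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
}

# Numerical power oracle for the two-group sample size: smallest n whose
# two-sided normal-test power reaches the target.
power_n_oracle <- function(delta, power = 0.9, alpha = 0.05) {
  za <- qnorm(1 - alpha / 2)
  pw <- function(n) {
    se <- sqrt(2 / n)
    pnorm(delta / se - za) + pnorm(-delta / se - za)
  }
  n <- 1L
  while (pw(n) < power && n < 1e7) n <- n + 1L
  n
}
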