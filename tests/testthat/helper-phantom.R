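# Shared fixtures, generated once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

# compact phantom for fast unit tests: coarser grid, 6 phases (ES exact at
# phase 4), otherwise the default anatomy
small_spec <- function(seed = 1L, ...) {
  args <- list(n_phases = 6L, sax_grid = 64L, pixel_spacing = 2.25,
               lax_grid = 64L, lax_spacing = 3, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

small_phantom <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- generate_study(small_spec())
  .fixtures$small
}

default_phantom <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generate_study(phantom_spec())
  .fixtures$default
}

# an arbitrary oblique orthonormal image plane
random_plane <- function(seed, n_rows = 32L, n_cols = 32L, row_spacing = 1.3,
                         col_spacing = 0.9, slab = 8) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  image_plane(origin = rnorm(3, 0, 40), row_dir = q[, 1L], col_dir = q[, 2L],
              row_spacing = row_spacing, col_spacing = col_spacing,
              slab_thickness = slab, n_rows = n_rows, n_cols = n_cols)
}

# truth masks of one stack phase as a list of matrices
truth_stack_masks <- function(g, phase) {
  n_sl <- length(g$study$sax$planes)
  grid <- g$truth$spec$sax_grid
  lapply(seq_len(n_sl), function(k)
    matrix(g$truth$masks$sax[, , k, phase], grid, grid))
}

# training/evaluation slices for the toy segmentation experiments:
# 64x64 ED-phase short-axis slices from phantoms with varied anatomy
toy_slices <- function(n_subj, seed0) {
  imgs <- list()
  msks <- list()
  for (i in seq_len(n_subj)) {
    set.seed(seed0 + i)
    sp <- phantom_spec(
      semi_axes_ed = c(runif(1, 18, 28), runif(1, 18, 28), runif(1, 38, 48)),
      wall_thickness = runif(1, 6, 10),
      ef_target = runif(1, 0.45, 0.7),
      n_phases = 2L, sax_grid = 64L, pixel_spacing = 2.25,
      lax_grid = 64L, lax_spacing = 3,
      pose = rigid_pose(runif(1, -30, 30), rnorm(3), rnorm(3, 0, 10)),
      noise_sd = 0.05, seed = seed0 + i)
    g <- generate_study(sp)
    for (k in seq_along(g$study$sax$planes)) {
      imgs[[length(imgs) + 1L]] <- g$study$sax$pixels[, , k, 1L]
      msks[[length(msks) + 1L]] <- matrix(g$truth$masks$sax[, , k, 1L],
                                          64L, 64L)
    }
  }
  list(images = simplify2array(imgs), masks = simplify2array(msks))
}

# varied-anatomy subjects for precision simulations
precision_subjects <- function(n_subj, seed0 = 1000L) {
  lapply(seq_len(n_subj), function(i)
    generate_study(random_phantom_spec(seed0 + i)))
}
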