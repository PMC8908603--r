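#' Rigid pose
#'
#' Convenience constructor for the rigid transform placing the phantom
#' ventricle in patient space: `p_patient = rotation %*% p_local + translation`.
#'
#' @param angle_deg rotation angle about `axis`, degrees.
#' @param axis length-3 rotation axis (need not be unit).
#' @param translation length-3 offset, mm.
#' @return list with `rotation` (3x3) and `translation`.
#' @export
rigid_pose <- function(angle_deg = 0, axis = c(0, 0, 1),
                       translation = c(0, 0, 0)) {
  th <- angle_deg * pi / 180
  u <- unitize(as.numeric(axis))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(rotation = R, translation = as.numeric(translation))
}

#' Phantom specification
#'
#' Parameters of the synthetic ventricle: a truncated-ellipsoid blood pool
#' with a uniform-thickness myocardial shell, contracting over the cardiac
#' cycle by isotropic scaling of the semi-axes (with the basal cut plane
#' scaling along, so every phase has a closed-form volume). Defaults emulate
#' a typical clinical cine prescription: 30 phases, 12 short-axis slices at
#' 8 mm inter-slice spacing, 1.5 mm in-plane pixels, and a left ventricle
#' with ~117 ml end-diastolic volume and 60% ejection fraction.
#'
#' @param semi_axes_ed length-3 (a, b, c) mm: ED blood-pool semi-axes; `c`
#'   lies along the long axis.
#' @param wall_thickness myocardial shell thickness at ED, mm.
#' @param truncation_fraction fraction of `c` at which the mitral valve plane
#'   cuts the ellipsoid (the basal cap above `z = truncation_fraction * c` is
#'   atrial and is trimmed away), in (0, 1).
#' @param ef_target ejection fraction in (0, 1); phase-wise scaling is solved
#'   so the analytic EF equals this exactly.
#' @param n_phases number of cardiac phases (>= 2).
#' @param n_sax_slices number of short-axis slices (>= 3).
#' @param sax_spacing inter-slice spacing, mm.
#' @param pixel_spacing SAx in-plane pixel size, mm.
#' @param sax_grid,lax_grid SAx / long-axis grid size (pixels per side).
#' @param lax_spacing long-axis in-plane pixel size, mm.
#' @param lax_angle_deg angle between the 2Ch and 4Ch planes about the long
#'   axis, degrees.
#' @param pose a [rigid_pose] placing the ventricle in patient space.
#' @param noise_sd grayscale Gaussian noise standard deviation.
#' @param seed integer RNG seed (determinism contract).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes_ed = c(25, 25, 50),
                         wall_thickness = 8,
                         truncation_fraction = 0.6,
                         ef_target = 0.6,
                         n_phases = 30L,
                         n_sax_slices = 13L,
                         sax_spacing = 8,
                         pixel_spacing = 1.5,
                         sax_grid = 96L,
                         lax_grid = 128L,
                         lax_spacing = 1.5,
                         lax_angle_deg = 60,
                         pose = rigid_pose(25, c(1, 2, 0.5), c(-30, 15, 40)),
                         noise_sd = 0.02,
                         seed = 1L) {
  if (any(semi_axes_ed <= 0) || wall_thickness <= 0)
    cmr_stop("spec_error", "semi-axes and wall thickness must be positive")
  if (truncation_fraction <= 0 || truncation_fraction >= 1)
    cmr_stop("spec_error", "truncation_fraction must be in (0, 1)")
  if (ef_target <= 0 || ef_target >= 1)
    cmr_stop("spec_error", "ef_target must be in (0, 1)")
  if (n_phases < 2 || n_sax_slices < 3)
    cmr_stop("spec_error", "need >= 2 phases and >= 3 SAx slices")
  structure(list(
    semi_axes_ed = as.numeric(semi_axes_ed),
    wall_thickness = wall_thickness,
    truncation_fraction = truncation_fraction,
    ef_target = ef_target,
    n_phases = as.integer(n_phases),
    n_sax_slices = as.integer(n_sax_slices),
    sax_spacing = sax_spacing, pixel_spacing = pixel_spacing,
    sax_grid = as.integer(sax_grid), lax_grid = as.integer(lax_grid),
    lax_spacing = lax_spacing, lax_angle_deg = lax_angle_deg,
    pose = pose, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Draw a phantom specification with randomised anatomy
#'
#' Samples a subject for simulation studies: blood-pool semi-axes uniform in
#' 20-28 mm (short axes) and 40-50 mm (long axis), wall thickness 6-10 mm,
#' ejection fraction 0.45-0.7, and a random pose — spanning a realistic
#' adult range. Acquisition parameters keep the [phantom_spec] defaults
#' unless overridden through `...`.
#'
#' @param seed integer; seeds both the anatomy draw and the generated study.
#' @param ... further arguments passed to [phantom_spec].
#' @return a `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, ...) {
  set.seed(seed)
  args <- list(
    semi_axes_ed = c(stats::runif(1, 20, 28), stats::runif(1, 20, 28),
                     stats::runif(1, 40, 50)),
    wall_thickness = stats::runif(1, 6, 10),
    ef_target = stats::runif(1, 0.45, 0.7),
    pose = rigid_pose(stats::runif(1, -30, 30), stats::rnorm(3),
                      stats::rnorm(3, 0, 10)),
    seed = as.integer(seed))
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

#' Volume of a truncated ellipsoid
#'
#' Closed-form volume of the ellipsoid `x^2/a^2 + y^2/b^2 + z^2/c^2 <= 1`
#' with a cap of height `h` removed from the +z pole:
#' `V = 4/3 pi a b c - pi a b h^2 (3c - h) / (3 c^2)`, converted to ml.
#' This is the analytic ground truth every volumetric stage is tested
#' against.
#'
#' @param a,b,c semi-axes, mm.
#' @param cut_height_h cap height removed, mm, in `[0, 2c]`.
#' @return volume in ml.
#' @examples
#' analytic_truncated_ellipsoid_volume(10, 10, 10, 0)   # sphere, 4.18879 ml
#' @export
analytic_truncated_ellipsoid_volume <- function(a, b, c, cut_height_h) {
  if (any(c(a, b, c) <= 0))
    cmr_stop("domain_error", "semi-axes must be positive")
  h <- cut_height_h
  if (any(h < 0) || any(h > 2 * c))
    cmr_stop("domain_error", "cut height must be in [0, 2c]")
  (4 / 3 * pi * a * b * c - pi * a * b * h^2 * (3 * c - h) / (3 * c^2)) / 1000
}

# ---- internal phantom machinery -------------------------------------------

#' @noRd
sax_z_start <- function(spec) {
  -(spec$semi_axes_ed[3] + spec$wall_thickness) - spec$sax_spacing / 4
}

#' @noRd
phase_scales <- function(spec) {
  s_es <- (1 - spec$ef_target)^(1 / 3)
  p <- seq_len(spec$n_phases) - 1L
  1 - (1 - s_es) * sin(pi * p / spec$n_phases)^2
}

#' @noRd
#' Wall thickness at a phase conserving shell volume (incompressible
#' myocardium): solve for w so outer-minus-inner truncated volumes equal the
#' ED shell volume. Exact at ED by construction.
phase_wall <- function(spec, s, wall_ml) {
  ax <- spec$semi_axes_ed * s
  f <- spec$truncation_fraction
  zc <- f * spec$semi_axes_ed[3] * s
  vin <- analytic_truncated_ellipsoid_volume(ax[1], ax[2], ax[3], ax[3] - zc)
  g <- function(w) {
    analytic_truncated_ellipsoid_volume(ax[1] + w, ax[2] + w, ax[3] + w,
                                        ax[3] + w - zc) - vin - wall_ml
  }
  stats::uniroot(g, c(1e-9, 4 * spec$wall_thickness + 20), tol = 1e-10)$root
}

#' @noRd
#' Build the acquisition planes (optionally under a prescription
#' perturbation applied to the planes only; anatomy is untouched).
build_planes <- function(spec, pert_rotation = diag(3),
                         pert_translation = c(0, 0, 0), slice_shift = 0) {
  R <- spec$pose$rotation
  t0 <- spec$pose$translation
  c_ed <- spec$semi_axes_ed[3]
  f <- spec$truncation_fraction
  sp <- spec$sax_spacing
  # stack must cover the epicardial apex (a wall thickness below the
  # blood-pool apex) through at least one slice above the valve plane
  z_start <- sax_z_start(spec)
  z_top <- z_start + (spec$n_sax_slices - 1L) * sp
  if (z_top < f * c_ed + sp / 2)
    cmr_stop("spec_error",
             "SAx stack cannot cover the ventricle plus one atrial slice")

  ps <- spec$pixel_spacing
  n <- spec$sax_grid
  half <- (n - 1) / 2
  mk_local <- function(origin_l, row_l, col_l, spacing, nn, slab) {
    image_plane(
      origin = as.numeric(R %*% origin_l) + t0,
      row_dir = as.numeric(R %*% row_l),
      col_dir = as.numeric(R %*% col_l),
      row_spacing = spacing, col_spacing = spacing,
      slab_thickness = slab, n_rows = nn, n_cols = nn
    )
  }
  sax <- lapply(seq_len(spec$n_sax_slices), function(k) {
    z <- z_start + (k - 1L) * sp
    mk_local(c(-half * ps, -half * ps, z), c(1, 0, 0), c(0, 1, 0), ps, n, sp)
  })
  nl <- spec$lax_grid
  lsp <- spec$lax_spacing
  halfl <- (nl - 1) / 2
  ch2 <- mk_local(c(-halfl * lsp, 0, -halfl * lsp), c(1, 0, 0), c(0, 0, 1),
                  lsp, nl, 6)
  th <- spec$lax_angle_deg * pi / 180
  u <- c(cos(th), sin(th), 0)
  ch4 <- mk_local(-halfl * lsp * u + c(0, 0, -halfl * lsp) * c(0, 0, 1),
                  u, c(0, 0, 1), lsp, nl, 6)

  # prescription perturbation: rigid move of the planes about the ventricle
  # centre, plus a through-plane shift of the SAx stack
  perturb <- function(pl) {
    p2 <- transform_plane(pl, pert_rotation,
                          t0 - as.numeric(pert_rotation %*% t0) +
                            pert_translation)
    p2
  }
  sax <- lapply(sax, perturb)
  if (slice_shift != 0) {
    nrm <- plane_normal(sax[[1L]])
    sax <- lapply(sax, function(pl) {
      pl$origin <- pl$origin + slice_shift * nrm
      pl
    })
  }
  list(sax = sax, ch2 = perturb(ch2), ch4 = perturb(ch4))
}

#' @noRd
#' Local-frame coordinates of all pixel centres of a plane (n x 3).
plane_local_coords <- function(plane, pose) {
  grid <- expand.grid(row = 0:(plane$n_rows - 1L), col = 0:(plane$n_cols - 1L))
  p <- pixel_to_patient(plane, grid$row, grid$col)
  sweep(p, 2L, pose$translation) %*% pose$rotation
}

#' @noRd
#' 3-class labels for one plane at one phase, from the analytic anatomy.
#' The blood pool and shell continue through the basal cut into the atrium
#' (full ellipsoids): basal inclusion is decided downstream by mitral-plane
#' trimming, mirroring how basal/atrial slices are fully annotated and then
#' trimmed.
rasterize_labels_local <- function(L, inner, outer) {
  qi <- (L[, 1] / inner[1])^2 + (L[, 2] / inner[2])^2 + (L[, 3] / inner[3])^2
  qo <- (L[, 1] / outer[1])^2 + (L[, 2] / outer[2])^2 + (L[, 3] / outer[3])^2
  lab <- integer(nrow(L))
  lab[qo <= 1] <- 2L
  lab[qi <= 1] <- 1L
  lab
}

#' @noRd
phantom_geometry <- function(spec) {
  s <- phase_scales(spec)
  axes <- spec$semi_axes_ed
  f <- spec$truncation_fraction
  wall_in <- analytic_truncated_ellipsoid_volume(
    axes[1], axes[2], axes[3], axes[3] * (1 - f))
  wall_out <- analytic_truncated_ellipsoid_volume(
    axes[1] + spec$wall_thickness, axes[2] + spec$wall_thickness,
    axes[3] + spec$wall_thickness,
    axes[3] + spec$wall_thickness - f * axes[3])
  wall_ml <- wall_out - wall_in
  walls <- vapply(s, function(si) phase_wall(spec, si, wall_ml), numeric(1))
  list(scales = s, walls = walls, wall_ml = wall_ml,
       cut_z = f * axes[3] * s,
       inner = t(vapply(s, function(si) axes * si, numeric(3))),
       outer = t(vapply(seq_along(s), function(i) axes * s[i] + walls[i],
                        numeric(3))))
}

#' @noRd
#' Landmark (mitral annulus) points of one long-axis view at one phase, in
#' the local frame: the cut plane meets the blood-pool surface on an ellipse;
#' the view plane (containing the long axis, in-plane direction u) picks two
#' diametric points off it.
mv_points_local <- function(u, inner, cut_z, c_phase) {
  fr <- cut_z / c_phase
  r <- sqrt((1 - fr^2) / ((u[1] / inner[1])^2 + (u[2] / inner[2])^2))
  rbind(r * u + c(0, 0, cut_z), -r * u + c(0, 0, cut_z))
}

#' @noRd
render_study <- function(spec, planes, geo, noise_seed) {
  n_ph <- spec$n_phases
  gray_levels <- c(0.1, 1.0, 0.5)  # background, blood, myocardium

  render_plane <- function(plane) {
    L <- plane_local_coords(plane, spec$pose)
    labs <- array(0L, dim = c(plane$n_rows, plane$n_cols, n_ph))
    gray <- array(0, dim = c(plane$n_rows, plane$n_cols, n_ph))
    for (p in seq_len(n_ph)) {
      lab <- rasterize_labels_local(L, geo$inner[p, ], geo$outer[p, ])
      labs[, , p] <- lab
      gray[, , p] <- gray_levels[lab + 1L]
    }
    list(labels = labs, gray = gray)
  }

  sax_r <- lapply(planes$sax, render_plane)
  ch2_r <- render_plane(planes$ch2)
  ch4_r <- render_plane(planes$ch4)

  set.seed(noise_seed)
  add_noise <- function(g) {
    if (spec$noise_sd <= 0) return(g)
    pmin(pmax(g + stats::rnorm(length(g), 0, spec$noise_sd), 0), 1)
  }
  nr <- spec$sax_grid
  sax_px <- array(0, dim = c(nr, nr, spec$n_sax_slices, n_ph))
  sax_lab <- array(0L, dim = c(nr, nr, spec$n_sax_slices, n_ph))
  for (k in seq_len(spec$n_sax_slices)) {
    sax_px[, , k, ] <- add_noise(sax_r[[k]]$gray)
    sax_lab[, , k, ] <- sax_r[[k]]$labels
  }
  ch2_px <- add_noise(ch2_r$gray)
  ch4_px <- add_noise(ch4_r$gray)

  # landmark pixel annotations: where the annulus points fall on each view's
  # pixel grid (content-anchored; moves with the image, not with the header)
  mv_px <- function(plane, u) {
    out <- array(NA_real_, dim = c(n_ph, 2L, 2L),
                 dimnames = list(NULL, NULL, c("row", "col")))
    for (p in seq_len(n_ph)) {
      pts_l <- mv_points_local(u, geo$inner[p, ], geo$cut_z[p],
                               geo$inner[p, 3])
      pts <- sweep(pts_l %*% t(spec$pose$rotation), 2L,
                   -spec$pose$translation)
      px <- patient_to_pixel(plane, pts)
      out[p, , "row"] <- px$row
      out[p, , "col"] <- px$col
    }
    out
  }
  th <- spec$lax_angle_deg * pi / 180
  u2 <- c(1, 0, 0)
  u4 <- c(cos(th), sin(th), 0)

  study <- structure(list(
    sax = list(planes = planes$sax, pixels = sax_px),
    ch2 = list(plane = planes$ch2, pixels = ch2_px,
               mv_px = mv_px(planes$ch2, u2)),
    ch4 = list(plane = planes$ch4, pixels = ch4_px,
               mv_px = mv_px(planes$ch4, u4)),
    n_phases = n_ph,
    phase_times = (seq_len(n_ph) - 1) / n_ph * 1000
  ), class = "cine_study")
  list(study = study, sax_labels = sax_lab,
       ch2_labels = ch2_r$labels, ch4_labels = ch4_r$labels)
}

#' Generate a synthetic multi-plane cine study
#'
#' Produces a `cine_study` (short-axis stack plus 2-chamber and 4-chamber
#' long-axis cines, with full plane geometry and grayscale pixel data) and a
#' `phantom_truth` holding the analytic ground truth: per-phase blood and
#' shell geometry, mitral valve plane and annulus points, 3-class label
#' masks, and closed-form EDV/ESV/EF/LVM. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `study` and `truth`.
#' @export
generate_study <- function(spec) {
  geo <- phantom_geometry(spec)
  planes <- build_planes(spec)
  rend <- render_study(spec, planes, geo, noise_seed = spec$seed)

  axes <- spec$semi_axes_ed
  f <- spec$truncation_fraction
  edv <- analytic_truncated_ellipsoid_volume(axes[1], axes[2], axes[3],
                                             axes[3] * (1 - f))
  s_es_idx <- which.min(geo$scales)
  esv <- edv * min(geo$scales)^3
  R <- spec$pose$rotation
  t0 <- spec$pose$translation
  th <- spec$lax_angle_deg * pi / 180
  to_patient <- function(pl) sweep(pl %*% t(R), 2L, -t0)

  n_ph <- spec$n_phases
  mv2 <- array(NA_real_, c(n_ph, 2L, 3L))
  mv4 <- array(NA_real_, c(n_ph, 2L, 3L))
  mv_planes <- vector("list", n_ph)
  for (p in seq_len(n_ph)) {
    mv2[p, , ] <- to_patient(mv_points_local(c(1, 0, 0), geo$inner[p, ],
                                             geo$cut_z[p], geo$inner[p, 3]))
    mv4[p, , ] <- to_patient(mv_points_local(c(cos(th), sin(th), 0),
                                             geo$inner[p, ], geo$cut_z[p],
                                             geo$inner[p, 3]))
    mv_planes[[p]] <- structure(list(
      point = as.numeric(R %*% c(0, 0, geo$cut_z[p])) + t0,
      normal = as.numeric(R %*% c(0, 0, -1)),   # ventricular side positive
      fit_residual_mm = 0
    ), class = "mv_plane")
  }

  z_mid <- sax_z_start(spec) +
    (spec$n_sax_slices %/% 2L) * spec$sax_spacing
  truth <- structure(list(
    spec = spec,
    scales = geo$scales, walls = geo$walls, cut_z = geo$cut_z,
    inner = geo$inner, outer = geo$outer,
    edv_ml = edv, esv_ml = esv,
    ef_pct = 100 * (edv - esv) / edv,
    myo_volume_ml_ed = geo$wall_ml,
    lvm_g = geo$wall_ml * 1.05,
    ed_index = 1L, es_index = as.integer(s_es_idx),
    mv_points_2ch = mv2, mv_points_4ch = mv4,
    mv_plane = mv_planes,
    masks = list(sax = rend$sax_labels, ch2 = rend$ch2_labels,
                 ch4 = rend$ch4_labels),
    axis_anchor = as.numeric(R %*% c(0, 0, z_mid)) + t0,
    apex_point = as.numeric(R %*% c(0, 0, -axes[3])) + t0,
    base_point = as.numeric(R %*% c(0, 0, axes[3])) + t0
  ), class = "phantom_truth")
  list(study = rend$study, truth = truth)
}

#' Simulate a re-scan with perturbed slice prescription
#'
#' The same underlying ventricle is re-imaged with planes prescribed slightly
#' differently — the intrinsic scan-rescan variability of cine CMR. The
#' perturbation is a random rigid move of all planes about the ventricle
#' centre (direction/axis drawn uniformly, magnitudes up to the stated
#' maxima) plus a through-plane shift of the SAx stack. The analytic ground
#' truth volumes are unchanged; masks and landmark annotations are
#' re-rendered for the new planes.
#'
#' @param study,truth a pair from [generate_study].
#' @param perturbation list with elements `translation` (mm), `rotation_deg`
#'   and `slice_shift` (mm): maximum perturbation magnitudes.
#' @param seed RNG seed for the perturbation draw and the re-rendered noise.
#' @return list with elements `study` and `truth`.
#' @export
rescan <- function(study, truth,
                   perturbation = list(translation = 0, rotation_deg = 0,
                                       slice_shift = 0),
                   seed = 1L) {
  spec <- truth$spec
  set.seed(seed)
  rand_unit <- function() {
    v <- stats::rnorm(3)
    unitize(v)
  }
  tr <- rand_unit() * stats::runif(1, 0, 1) * perturbation$translation
  rot <- rigid_pose(stats::runif(1, -1, 1) * perturbation$rotation_deg,
                    rand_unit())$rotation
  shift <- stats::runif(1, -1, 1) * perturbation$slice_shift
  if (perturbation$translation == 0) tr <- c(0, 0, 0)
  if (perturbation$rotation_deg == 0) rot <- diag(3)
  if (perturbation$slice_shift == 0) shift <- 0

  geo <- phantom_geometry(spec)
  planes <- build_planes(spec, pert_rotation = rot, pert_translation = tr,
                         slice_shift = shift)
  rend <- render_study(spec, planes, geo, noise_seed = seed)
  truth2 <- truth
  truth2$masks <- list(sax = rend$sax_labels, ch2 = rend$ch2_labels,
                       ch4 = rend$ch4_labels)
  list(study = rend$study, truth = truth2)
}

#' Simulate a breath-hold shift between short- and long-axis acquisition
#'
#' Cine views are acquired in separate breath-holds; if the diaphragm
#' position differs, the long-axis acquisitions are displaced relative to
#' the short-axis stack. This is modelled by translating the long-axis plane
#' headers by `offset` while leaving their pixel content (and pixel-space
#' landmark annotations) untouched — so every landmark decoded from a
#' long-axis image maps to a patient position shifted by `offset`, and the
#' fitted mitral plane trims the wrong cap of the ventricle.
#'
#' @param study a `cine_study`.
#' @param offset length-3 translation, mm.
#' @return the modified `cine_study`.
#' @export
breathhold_offset <- function(study, offset) {
  offset <- as.numeric(offset)
  study$ch2$plane$origin <- study$ch2$plane$origin + offset
  study$ch4$plane$origin <- study$ch4$plane$origin + offset
  study
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf("<cine_study: %d SAx slices x %d phases, 2Ch + 4Ch>\n",
              length(x$sax$planes), x$n_phases))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth: EDV %.1f ml, ESV %.1f ml, EF %.1f%%, LVM %.1f g>\n",
    x$edv_ml, x$esv_ml, x$ef_pct, x$lvm_g))
  invisible(x)
}
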