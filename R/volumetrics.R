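#' Volume of one labelled slice, optionally trimmed by the mitral plane
#'
#' Standard slab (Simpson's disc) volumetry: each pixel with the requested
#' label contributes `pixel_area * slab_thickness`, where the slab extends
#' half the inter-slice spacing to either side of the slice plane. When a
#' mitral valve plane is supplied, each pixel's slab column is clipped
#' against it: the contribution is scaled by the fraction of the column on
#' the ventricular (positive-normal) side, clamped to \[0, 1\]. Fractional
#' per-column clipping (rather than whole-slice inclusion/exclusion) is what
#' makes stacked volumes converge to the analytic truncated-ellipsoid truth.
#'
#' @param mask 2D integer label array (0 background, 1 blood, 2 myocardium).
#' @param plane the [image_plane] the mask lives on.
#' @param label which label to integrate (default 1, blood pool).
#' @param mv_plane optional `mv_plane`; volume below it (atrial side) is
#'   discarded.
#' @return volume in ml.
#' @export
slice_volume <- function(mask, plane, label = 1L, mv_plane = NULL) {
  if (!all(dim(mask) == c(plane$n_rows, plane$n_cols)))
    cmr_stop("shape_error", "mask shape does not match plane grid")
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  vox_ml <- plane$row_spacing * plane$col_spacing * plane$slab_thickness / 1000
  if (is.null(mv_plane)) return(nrow(idx) * vox_ml)
  centres <- pixel_to_patient(plane, idx[, 1L] - 1, idx[, 2L] - 1)
  d0 <- mv_signed_distance(mv_plane, centres)
  # rate of change of signed distance along the slab column direction
  g <- sum(mv_plane$normal * plane_normal(plane))
  t <- plane$slab_thickness
  f <- if (abs(g) < 1e-12) as.numeric(d0 > 0) else {
    pmin(pmax(0.5 + d0 / (t * abs(g)), 0), 1)
  }
  sum(f) * vox_ml
}

#' Volume of a short-axis stack
#'
#' Sums [slice_volume] over a stack of parallel, uniformly spaced slices.
#' The slab thickness of each slice is the inter-slice spacing, so slabs
#' tile the covered range contiguously (gaps included; anything else double
#' counts or leaves holes).
#'
#' @param masks list of 2D label arrays, one per slice.
#' @param planes list of [image_plane]s (parallel within `angle_tol` rad,
#'   spacing uniform within `spacing_tol` relative).
#' @param label label to integrate.
#' @param mv_plane optional `mv_plane` used to trim the basal volume.
#' @param angle_tol,spacing_tol stack-regularity tolerances.
#' @return volume in ml.
#' @export
stack_volume <- function(masks, planes, label = 1L, mv_plane = NULL,
                         angle_tol = 1e-3, spacing_tol = 0.01) {
  if (length(masks) != length(planes))
    cmr_stop("shape_error", "one mask per plane required")
  n <- length(planes)
  nrm <- plane_normal(planes[[1L]])
  for (pl in planes[-1L]) {
    a <- acos(pmin(1, abs(sum(plane_normal(pl) * nrm))))
    if (a > angle_tol)
      cmr_stop("geometry_error", "stack slices are not parallel")
  }
  if (n > 2L) {
    pos <- vapply(planes, function(pl) sum(pl$origin * nrm), numeric(1))
    gaps <- diff(sort(pos))
    if (max(gaps) - min(gaps) > spacing_tol * mean(gaps))
      cmr_stop("geometry_error", "stack spacing is not uniform")
  }
  sum(vapply(seq_len(n), function(k) {
    slice_volume(masks[[k]], planes[[k]], label = label, mv_plane = mv_plane)
  }, numeric(1)))
}

#' Select end-diastolic and end-systolic phases
#'
#' End-diastole is the phase with the largest blood volume and end-systole
#' the phase with the smallest. Ties are broken by the lowest phase index.
#'
#' @param blood_ml numeric vector of per-phase blood volumes, ml.
#' @return list with `ed_index` and `es_index` (1-based phase indices).
#' @export
select_phases <- function(blood_ml) {
  if (length(blood_ml) < 2L)
    cmr_stop("data_error", "need at least two phases")
  if (any(!is.finite(blood_ml)))
    cmr_stop("data_error", "non-finite blood volume")
  list(ed_index = which.max(blood_ml), es_index = which.min(blood_ml))
}

#' Derive LV metrics from phase volumes
#'
#' @param blood_ml per-phase blood volumes, ml.
#' @param myo_ml_ed myocardial volume at end-diastole, ml.
#' @param density_g_per_ml myocardial density used for mass (the standard
#'   CMR convention, 1.05 g/ml).
#' @return object of class `lv_metrics`: `edv_ml`, `esv_ml`, `sv_ml`,
#'   `ef_pct`, `lvm_g`, `ed_index`, `es_index`.
#' @export
compute_metrics <- function(blood_ml, myo_ml_ed, density_g_per_ml = 1.05) {
  ph <- select_phases(blood_ml)
  edv <- blood_ml[ph$ed_index]
  esv <- blood_ml[ph$es_index]
  if (edv <= 0) cmr_stop("data_error", "end-diastolic volume must be positive")
  sv <- edv - esv
  structure(list(
    edv_ml = edv, esv_ml = esv, sv_ml = sv,
    ef_pct = 100 * sv / edv,
    lvm_g = myo_ml_ed * density_g_per_ml,
    ed_index = ph$ed_index, es_index = ph$es_index
  ), class = "lv_metrics")
}

#' @export
print.lv_metrics <- function(x, ...) {
  cat(sprintf(
    "LV metrics: EDV %.1f ml | ESV %.1f ml | SV %.1f ml | EF %.1f%% | LVM %.1f g\n",
    x$edv_ml, x$esv_ml, x$sv_ml, x$ef_pct, x$lvm_g))
  cat(sprintf("  ED phase %d, ES phase %d\n", x$ed_index, x$es_index))
  invisible(x)
}

#' Automated plausibility checks on a segmented stack
#'
#' Automated surrogate for visual review of anatomically incorrect
#' segmentations: a flag is raised whenever a defect affects at least
#' `volume_threshold` (default 5%) of the overall cardiac volume.
#' Checks per ED-phase slice: more than one blood-pool connected component;
#' a slice-to-slice blood area jump; myocardium not adjacent to the blood
#' pool; and (when supplied) a mitral-plane fit residual above
#' `residual_threshold` mm. Each flag carries the affected volume fraction
#' where defined.
#'
#' @param masks list of 2D label arrays (one stack phase, typically ED).
#' @param planes matching list of [image_plane]s.
#' @param volume_threshold fraction of total volume a defect must reach.
#' @param mv_fit_residual optional mitral-plane RMS residual, mm.
#' @param residual_threshold flag threshold for the residual, mm.
#' @return data.frame with columns `flag`, `slice`, `fraction`.
#' @export
plausibility_flags <- function(masks, planes, volume_threshold = 0.05,
                               mv_fit_residual = NULL,
                               residual_threshold = 3) {
  flags <- list()
  add <- function(flag, slice, fraction) {
    flags[[length(flags) + 1L]] <<- data.frame(
      flag = flag, slice = slice, fraction = fraction)
  }
  areas <- vapply(seq_along(masks), function(k) {
    sum(masks[[k]] == 1L) * planes[[k]]$row_spacing * planes[[k]]$col_spacing
  }, numeric(1))
  vols <- areas * vapply(planes, `[[`, numeric(1), "slab_thickness")
  total <- sum(vols) + sum(vapply(seq_along(masks), function(k) {
    sum(masks[[k]] == 2L) * planes[[k]]$row_spacing *
      planes[[k]]$col_spacing * planes[[k]]$slab_thickness
  }, numeric(1)))
  if (total <= 0) total <- Inf

  for (k in seq_along(masks)) {
    m <- masks[[k]]
    blood <- m == 1L
    if (any(blood)) {
      lab <- EBImage::bwlabel(blood * 1)
      ncomp <- max(lab)
      if (ncomp > 1L) {
        # the trusted component is the one supported by the adjacent
        # slices' blood pools; everything else is a candidate artifact
        ref <- matrix(FALSE, nrow(m), ncol(m))
        for (kk in c(k - 1L, k + 1L)) {
          if (kk >= 1L && kk <= length(masks) &&
              all(dim(masks[[kk]]) == dim(m)))
            ref <- ref | masks[[kk]] == 1L
        }
        sizes <- tabulate(lab[lab > 0], nbins = ncomp)
        overlap <- vapply(seq_len(ncomp), function(ci)
          sum(ref[lab == ci]), numeric(1))
        keep <- if (any(overlap > 0)) which.max(overlap)
        else which.max(sizes)
        extra <- sum(sizes[-keep]) * planes[[k]]$row_spacing *
          planes[[k]]$col_spacing * planes[[k]]$slab_thickness
        if (extra / total >= volume_threshold)
          add("multiple_blood_components", k, extra / total)
      }
      if (any(m == 2L)) {
        # myocardium should touch the blood pool: dilate blood by one pixel
        dil <- EBImage::dilate(blood * 1, EBImage::makeBrush(3, "box"))
        if (!any(dil > 0 & m == 2L)) add("myocardium_not_adjacent", k,
                                         NA_real_)
      }
    }
  }
  if (length(areas) > 2L) {
    interior <- 2:(length(areas) - 1L)
    for (k in interior) {
      expected <- (areas[k - 1L] + areas[k + 1L]) / 2
      jump <- abs(areas[k] - expected) *
        planes[[k]]$slab_thickness / total
      if (jump >= volume_threshold) add("blood_area_jump", k, jump)
    }
  }
  if (!is.null(mv_fit_residual) && mv_fit_residual > residual_threshold)
    add("mv_plane_residual", NA_integer_, NA_real_)
  if (length(flags) == 0L)
    data.frame(flag = character(), slice = integer(), fraction = numeric())
  else do.call(rbind, flags)
}
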