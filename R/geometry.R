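#' Image plane geometry (DICOM convention)
#'
#' An `image_plane` records where one acquired slice sits in patient space,
#' using the DICOM convention: `origin` is the patient-coordinate (LPS)
#' position of the *centre* of pixel (0, 0), `row_dir`/`col_dir` are unit
#' vectors along increasing row and column index, and spacings are in
#' mm/pixel. `slab_thickness` is the through-plane extent one slice accounts
#' for (slice thickness plus gap, i.e. the inter-slice spacing in a stack).
#' Pixel indices are 0-based throughout, matching DICOM.
#'
#' @param origin numeric length-3, mm, patient coordinates of pixel (0,0).
#' @param row_dir,col_dir unit length-3 direction vectors (orthogonal).
#' @param row_spacing,col_spacing pixel spacing in mm (> 0).
#' @param slab_thickness through-plane slab extent in mm (> 0).
#' @param n_rows,n_cols grid size (positive integers).
#' @return An object of class `image_plane`.
#' @examples
#' pl <- image_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 1, 1, 8, 64, 64)
#' pixel_to_patient(pl, 3, 4)
#' @export
image_plane <- function(origin, row_dir, col_dir, row_spacing, col_spacing,
                        slab_thickness, n_rows, n_cols) {
  origin <- as.numeric(origin)
  row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  stopifnot(length(origin) == 3L, length(row_dir) == 3L, length(col_dir) == 3L)
  if (abs(vnorm(row_dir) - 1) > 1e-9 || abs(vnorm(col_dir) - 1) > 1e-9)
    cmr_stop("domain_error", "row_dir and col_dir must be unit vectors")
  if (abs(sum(row_dir * col_dir)) > 1e-9)
    cmr_stop("domain_error", "row_dir and col_dir must be orthogonal")
  if (row_spacing <= 0 || col_spacing <= 0 || slab_thickness <= 0)
    cmr_stop("domain_error", "spacings and slab_thickness must be positive")
  if (n_rows < 1 || n_cols < 1)
    cmr_stop("domain_error", "grid dimensions must be positive")
  structure(list(
    origin = origin, row_dir = row_dir, col_dir = col_dir,
    row_spacing = as.numeric(row_spacing), col_spacing = as.numeric(col_spacing),
    slab_thickness = as.numeric(slab_thickness),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
  ), class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane %dx%d, %.3gx%.3g mm, slab %.3g mm>\n",
              x$n_rows, x$n_cols, x$row_spacing, x$col_spacing,
              x$slab_thickness))
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Plane normal
#'
#' Unit normal of an image plane, defined as `row_dir x col_dir`.
#' @param plane an [image_plane].
#' @return unit length-3 vector.
#' @export
plane_normal <- function(plane) cross3(plane$row_dir, plane$col_dir)

#' Map pixel indices to patient coordinates
#'
#' Affine DICOM pixel-to-patient mapping. Indices may be fractional
#' (sub-pixel positions).
#'
#' @param plane an [image_plane].
#' @param row,col 0-based pixel indices (numeric vectors of equal length).
#' @return an n x 3 matrix of patient coordinates in mm (a plain numeric
#'   vector when a single point is mapped).
#' @export
pixel_to_patient <- function(plane, row, col) {
  if (length(row) != length(col))
    cmr_stop("shape_error", "row and col must have equal length")
  p <- outer(row * plane$row_spacing, plane$row_dir) +
    outer(col * plane$col_spacing, plane$col_dir)
  p <- sweep(p, 2L, -plane$origin)
  if (length(row) == 1L) as.numeric(p) else p
}

#' Map patient coordinates to pixel indices
#'
#' Inverse of [pixel_to_patient]: returns fractional (row, col) indices plus
#' the signed out-of-plane distance along the plane normal, so that
#' `pixel_to_patient(plane, row, col) + out_of_plane * plane_normal(plane)`
#' reconstructs the input point.
#'
#' @param plane an [image_plane].
#' @param p length-3 point or n x 3 matrix of points, mm.
#' @return a named list with `row`, `col`, `out_of_plane` (vectors).
#' @export
patient_to_pixel <- function(plane, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  d <- sweep(p, 2L, plane$origin)
  list(
    row = as.numeric(d %*% plane$row_dir) / plane$row_spacing,
    col = as.numeric(d %*% plane$col_dir) / plane$col_spacing,
    out_of_plane = as.numeric(d %*% plane_normal(plane))
  )
}

#' Intersection line of two image planes
#'
#' @param a,b [image_plane] objects; must not be (near-)parallel.
#' @param tol parallelism tolerance on `|n_a x n_b|` (default 1e-6).
#' @return a list of class `line3d` with unit `direction` and a `point` lying
#'   on both planes.
#' @export
plane_intersection_line <- function(a, b, tol = 1e-6) {
  na <- plane_normal(a)
  nb <- plane_normal(b)
  d <- cross3(na, nb)
  if (vnorm(d) <= tol)
    cmr_stop("parallel_planes_error",
             "planes are parallel (or nearly so); no intersection line")
  d <- unitize(d)
  # point on the line: solve n_a.x = n_a.o_a, n_b.x = n_b.o_b, d.x = 0
  A <- rbind(na, nb, d)
  rhs <- c(sum(na * a$origin), sum(nb * b$origin), 0)
  p <- solve(A, rhs)
  structure(list(point = as.numeric(p), direction = d), class = "line3d")
}

#' Common point of three image planes
#'
#' Solves the 3x3 linear system `n_i . x = n_i . o_i`. Used to anchor the
#' canonical reference frame at the intersection of the short-axis stack with
#' the two long-axis views.
#'
#' @param sax,ch2,ch4 [image_plane] objects with linearly independent normals.
#' @param tol degeneracy tolerance on the determinant of the normal matrix.
#' @return length-3 point, mm.
#' @export
three_plane_point <- function(sax, ch2, ch4, tol = 1e-6) {
  A <- rbind(plane_normal(sax), plane_normal(ch2), plane_normal(ch4))
  if (abs(det(A)) <= tol)
    cmr_stop("degenerate_geometry_error",
             "plane normals are not linearly independent")
  rhs <- c(sum(A[1L, ] * sax$origin), sum(A[2L, ] * ch2$origin),
           sum(A[3L, ] * ch4$origin))
  as.numeric(solve(A, rhs))
}

#' Build the spatial normalisation transform
#'
#' Constructs the rigid transform into the canonical reference frame used to
#' standardise network input: the intersection point of the (mid) short-axis
#' plane with the 2-chamber and 4-chamber planes maps to the origin, the
#' SAx/2Ch intersection line maps onto the y-axis (so the outflow tract is
#' always oriented the same way), and the SAx normal maps onto the z-axis.
#' In-plane resampling to `target_spacing` (1 mm) is done by
#' [resample_plane].
#'
#' The z-sign is ambiguous (either SAx normal orientation is a valid frame);
#' it is resolved so that `apex_reference` (a patient-space point on the
#' apical side of the stack, e.g. the centre of the apex-most slice) maps to
#' negative z relative to the anchor point, or equivalently so that
#' `ventricular_reference` (a point basal/ventricular-positive side) maps to
#' positive z. When neither is given the orientation implied by the SAx
#' normal is kept.
#'
#' @param sax representative short-axis [image_plane] (conventionally the mid
#'   stack slice).
#' @param ch2,ch4 long-axis [image_plane]s.
#' @param ventricular_reference optional length-3 patient point that must map
#'   to z > 0.
#' @param apex_reference optional length-3 patient point on the apical side
#'   that must map to z < 0 (used when `ventricular_reference` is NULL).
#' @param target_spacing in-plane pixel size after resampling, mm.
#' @return list of class `normalization_transform` with fields `rotation`
#'   (3x3, det +1), `translation` (length 3) and `target_spacing`; the map is
#'   `x -> rotation %*% x + translation`.
#' @export
build_normalization <- function(sax, ch2, ch4, ventricular_reference = NULL,
                                apex_reference = NULL, target_spacing = 1.0) {
  anchor <- three_plane_point(sax, ch2, ch4)
  ns <- plane_normal(sax)
  n2 <- plane_normal(ch2)
  d <- cross3(ns, n2)
  if (vnorm(d) <= 1e-6)
    cmr_stop("parallel_planes_error", "SAx and 2Ch planes are parallel")
  yhat <- unitize(d)            # SAx/2Ch intersection direction
  zhat <- ns                    # SAx normal
  if (!is.null(ventricular_reference)) {
    if (sum((as.numeric(ventricular_reference) - anchor) * zhat) < 0)
      zhat <- -zhat
  } else if (!is.null(apex_reference)) {
    if (sum((as.numeric(apex_reference) - anchor) * zhat) > 0)
      zhat <- -zhat
  }
  xhat <- cross3(yhat, zhat)    # right-handed completion
  rotation <- rbind(xhat, yhat, zhat)
  dimnames(rotation) <- NULL
  structure(list(
    rotation = rotation,
    translation = as.numeric(-rotation %*% anchor),
    target_spacing = target_spacing
  ), class = "normalization_transform")
}

#' Apply a normalisation transform to points
#'
#' @param transform a `normalization_transform`.
#' @param p length-3 point or n x 3 matrix.
#' @param inverse apply the inverse map.
#' @return transformed point(s), same shape as input.
#' @export
apply_transform <- function(transform, p, inverse = FALSE) {
  single <- !is.matrix(p)
  p <- if (single) matrix(p, ncol = 3L) else p
  out <- if (inverse) {
    sweep(p, 2L, transform$translation) %*% transform$rotation
  } else {
    sweep(p %*% t(transform$rotation), 2L, -transform$translation)
  }
  if (single) as.numeric(out) else out
}

#' Transform an image plane's geometry by a rigid map
#'
#' Returns the same physical plane expressed in the transformed frame (or,
#' equivalently, the plane rigidly moved by the map). Grid and spacings are
#' unchanged.
#' @param plane an [image_plane].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector, mm.
#' @return an [image_plane].
#' @export
transform_plane <- function(plane, rotation, translation = c(0, 0, 0)) {
  image_plane(
    origin = as.numeric(rotation %*% plane$origin) + translation,
    row_dir = as.numeric(rotation %*% plane$row_dir),
    col_dir = as.numeric(rotation %*% plane$col_dir),
    row_spacing = plane$row_spacing, col_spacing = plane$col_spacing,
    slab_thickness = plane$slab_thickness,
    n_rows = plane$n_rows, n_cols = plane$n_cols
  )
}
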