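#' @keywords internal
#' Bilinear sampling of a 2D array at fractional (row, col) positions.
#' Positions are 0-based; samples outside the grid return `fill`.
#' @noRd
sample_bilinear <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  # clamp corner indices independently (out-of-grid positions get `fill`;
  # the tolerance keeps exact grid points that round to -1e-16 inside)
  ra <- pmin.int(pmax.int(r0, 0), nr - 1)
  rb <- pmin.int(pmax.int(r0 + 1, 0), nr - 1)
  ca <- pmin.int(pmax.int(c0, 0), nc - 1)
  cb <- pmin.int(pmax.int(c0 + 1, 0), nc - 1)
  v <- (1 - fr) * ((1 - fc) * img[ra + 1 + nr * ca] + fc * img[ra + 1 + nr * cb]) +
    fr * ((1 - fc) * img[rb + 1 + nr * ca] + fc * img[rb + 1 + nr * cb])
  eps <- 1e-9
  v[row < -eps | row > nr - 1 + eps | col < -eps | col > nc - 1 + eps] <- fill
  v
}

#' @noRd
sample_nearest <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r <- round(row); c <- round(col)
  inside <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  v <- rep(fill, length(row))
  v[inside] <- img[cbind(r[inside] + 1, c[inside] + 1)]
  v
}

#' @keywords internal
#' In-plane axes of a plane after normalisation: project the two canonical
#' axes most orthogonal to the plane normal onto the plane. Returns patient-
#' space unit row/col directions; row takes the lower-index canonical axis so
#' that an exactly canonical short-axis plane keeps normal +z.
#' @noRd
canonical_inplane_axes <- function(plane, transform) {
  n <- plane_normal(plane)
  ncan <- as.numeric(transform$rotation %*% n)
  k <- which.max(abs(ncan))
  ax <- setdiff(1:3, k)
  proj <- function(i) {
    e <- c(0, 0, 0); e[i] <- 1
    v <- e - sum(e * ncan) * ncan / sum(ncan^2)
    unitize(as.numeric(t(transform$rotation) %*% v))
  }
  row_dir <- proj(ax[1L])
  col_dir <- proj(ax[2L])
  # re-orthogonalise col against row (exact when the normal maps to an axis)
  col_dir <- unitize(col_dir - sum(col_dir * row_dir) * row_dir)
  list(row_dir = row_dir, col_dir = col_dir)
}

#' Resample one slice in-plane to the canonical grid
#'
#' Regrids a slice (same physical plane, new pixel lattice) so that after
#' normalisation its in-plane axes align with the canonical frame and the
#' pixel size equals `transform$target_spacing` (1 mm by default). Grayscale
#' images use bilinear interpolation; label masks must use nearest-neighbour
#' so only input labels appear in the output. Resampling is strictly
#' in-plane: no through-plane interpolation is performed.
#'
#' @param image 2D numeric array on `plane`'s grid.
#' @param plane an [image_plane].
#' @param transform a `normalization_transform` from [build_normalization].
#' @param interpolation `"linear"` (grayscale) or `"nearest"` (labels).
#' @param fill value for pixels sampled outside the input grid.
#' @return list with `image` (2D array) and `plane` (the new [image_plane],
#'   still expressed in patient coordinates).
#' @export
resample_plane <- function(image, plane, transform,
                           interpolation = c("linear", "nearest"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  if (!is.matrix(image) || nrow(image) != plane$n_rows ||
      ncol(image) != plane$n_cols)
    cmr_stop("shape_error", "image shape does not match plane grid")
  new_plane <- resampled_plane_geometry(plane, transform)
  n_rows <- new_plane$n_rows
  n_cols <- new_plane$n_cols

  # sample the old image at the patient positions of the new pixel centres
  grid <- expand.grid(row = 0:(n_rows - 1L), col = 0:(n_cols - 1L))
  pts <- pixel_to_patient(new_plane, grid$row, grid$col)
  px <- patient_to_pixel(plane, pts)
  vals <- if (interpolation == "linear") {
    sample_bilinear(image, px$row, px$col, fill = fill)
  } else {
    sample_nearest(image, px$row, px$col, fill = fill)
  }
  out <- matrix(vals, nrow = n_rows, ncol = n_cols)
  list(image = out, plane = new_plane)
}

#' Canonical-grid geometry of a resampled plane
#'
#' The [image_plane] that [resample_plane] would produce, without touching
#' pixel data: same physical plane, in-plane axes aligned with the canonical
#' frame, pixel size `transform$target_spacing`, grid covering the original
#' footprint.
#'
#' @param plane an [image_plane].
#' @param transform a `normalization_transform`.
#' @return an [image_plane].
#' @export
resampled_plane_geometry <- function(plane, transform) {
  sp <- transform$target_spacing
  axes <- canonical_inplane_axes(plane, transform)
  corners <- pixel_to_patient(
    plane,
    row = c(0, 0, plane$n_rows - 1, plane$n_rows - 1),
    col = c(0, plane$n_cols - 1, 0, plane$n_cols - 1)
  )
  rel <- sweep(corners, 2L, plane$origin)
  u <- as.numeric(rel %*% axes$row_dir)   # mm along new row axis
  v <- as.numeric(rel %*% axes$col_dir)
  u0 <- min(u); v0 <- min(v)
  # small slack keeps the grid size stable under last-bit geometry noise
  image_plane(
    origin = plane$origin + u0 * axes$row_dir + v0 * axes$col_dir,
    row_dir = axes$row_dir, col_dir = axes$col_dir,
    row_spacing = sp, col_spacing = sp,
    slab_thickness = plane$slab_thickness,
    n_rows = floor((max(u) - u0) / sp + 0.5 + 1e-9) + 1L,
    n_cols = floor((max(v) - v0) / sp + 0.5 + 1e-9) + 1L
  )
}
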