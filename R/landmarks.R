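#' Encode a landmark as a Gaussian-weighted distance map
#'
#' The regression target used for mitral annular point localisation: each
#' pixel holds `exp(-d^2 / (2 sigma^2))` where `d` is the in-plane Euclidean
#' distance (mm) from the pixel centre to the landmark. The map peaks at 1 at
#' the landmark. Predicting this map is more robust than regressing the
#' coordinates directly.
#'
#' @param plane an [image_plane].
#' @param point_3d length-3 patient point; must lie within `max_oop` of the
#'   plane (any out-of-plane component is discarded with a warning).
#' @param sigma Gaussian width, mm (default 5).
#' @param max_oop tolerated out-of-plane distance, mm.
#' @return object of class `landmark_map`: list with `values` (2D array in
#'   \[0, 1\]) and `sigma`.
#' @export
encode_landmark <- function(plane, point_3d, sigma = 5, max_oop = 1) {
  px <- patient_to_pixel(plane, point_3d)
  if (abs(px$out_of_plane) > max_oop)
    warning(sprintf("landmark lies %.2f mm out of plane; projecting",
                    px$out_of_plane))
  rows <- 0:(plane$n_rows - 1L)
  cols <- 0:(plane$n_cols - 1L)
  du <- (rows - px$row) * plane$row_spacing
  dv <- (cols - px$col) * plane$col_spacing
  d2 <- outer(du^2, dv^2, "+")
  structure(list(values = exp(-d2 / (2 * sigma^2)), sigma = sigma),
            class = "landmark_map")
}

#' Decode a landmark map to a patient-space point
#'
#' Inverse of [encode_landmark]: the peak pixel is found (ties broken by
#' lowest (row, col) in lexicographic order) and refined to sub-pixel
#' precision by an intensity-weighted centroid over a window of half-width
#' `ceiling(sigma)` pixels, then mapped to patient coordinates.
#'
#' @param map a `landmark_map` (or plain 2D array of values).
#' @param plane the [image_plane] the map lives on.
#' @param min_peak minimum acceptable peak value; below it the landmark is
#'   declared absent (`no_peak_error`), e.g. when the annulus is not in view.
#' @return length-3 patient point, mm.
#' @export
decode_landmark <- function(map, plane, min_peak = 0.1) {
  values <- if (inherits(map, "landmark_map")) map$values else map
  sigma <- if (inherits(map, "landmark_map")) map$sigma else 5
  mx <- max(values)
  if (!is.finite(mx) || mx <= min_peak)
    cmr_stop("no_peak_error", "no landmark peak found in map")
  idx <- which(values == mx)
  # column-major order already gives lexicographic-by-(col,row); enforce
  # (row, col) lexicographic tie-break explicitly
  rc <- arrayInd(idx, dim(values))
  ord <- order(rc[, 1L], rc[, 2L])
  r0 <- rc[ord[1L], 1L]
  c0 <- rc[ord[1L], 2L]
  w <- ceiling(sigma / min(plane$row_spacing, plane$col_spacing))
  rr <- max(1L, r0 - w):min(nrow(values), r0 + w)
  cc <- max(1L, c0 - w):min(ncol(values), c0 + w)
  win <- values[rr, cc, drop = FALSE]
  tot <- sum(win)
  row <- sum(rowSums(win) * rr) / tot - 1
  col <- sum(colSums(win) * cc) / tot - 1
  pixel_to_patient(plane, row, col)
}

#' Fit the mitral valve plane to annulus points
#'
#' Total-least-squares (orthogonal regression) plane through >= 3 annulus
#' points: the plane passes through the centroid with normal given by the
#' smallest right singular vector of the centred point matrix, minimising the
#' sum of squared orthogonal distances. The normal is oriented so the
#' ventricle (given by `ventricular_reference`) lies on the positive side.
#' The RMS point-to-plane residual is reported as a quality signal: with the
#' usual two points from each of the 2Ch and 4Ch views the fit is
#' overdetermined by one, and a large residual indicates the two views
#' disagree (e.g. a breath-hold shift between acquisitions).
#'
#' @param points n x 3 matrix (n >= 3) of annulus points, mm.
#' @param ventricular_reference length-3 point on the ventricular (apical)
#'   side of the annulus.
#' @return object of class `mv_plane`: list with `point`, unit `normal`
#'   (ventricular side positive), and `fit_residual_mm`.
#' @export
fit_mv_plane <- function(points, ventricular_reference) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L)
    cmr_stop("data_error", "need an n x 3 matrix with n >= 3 points")
  centroid <- colMeans(points)
  X <- sweep(points, 2L, centroid)
  sv <- svd(X)
  if (sv$d[2L] <= 1e-6)
    cmr_stop("collinear_points_error",
             "annulus points are collinear; plane undetermined")
  normal <- sv$v[, 3L]
  if (sum((as.numeric(ventricular_reference) - centroid) * normal) < 0)
    normal <- -normal
  res <- sqrt(mean((X %*% normal)^2))
  structure(list(point = as.numeric(centroid), normal = as.numeric(normal),
                 fit_residual_mm = res),
            class = "mv_plane")
}

#' Signed distance to a mitral valve plane
#'
#' Positive on the ventricular side.
#' @param mv an `mv_plane`.
#' @param p length-3 point or n x 3 matrix.
#' @return numeric vector of signed distances, mm.
#' @export
mv_signed_distance <- function(mv, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3L)
  as.numeric(sweep(p, 2L, mv$point) %*% mv$normal)
}

#' @export
print.mv_plane <- function(x, ...) {
  cat(sprintf("<mv_plane through (%.1f, %.1f, %.1f), residual %.3g mm>\n",
              x$point[1], x$point[2], x$point[3], x$fit_residual_mm))
  invisible(x)
}
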