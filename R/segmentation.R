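#' Spatial augmentation of an (image, mask) pair
#'
#' Applies one random similarity transform — scaling, rotation and
#' translation about the image centre, drawn uniformly within the configured
#' ranges — identically to the image (bilinear interpolation) and the label
#' mask (nearest neighbour, so only input labels appear). Deterministic
#' given `seed`. Zero ranges give the identity.
#'
#' @param image 2D numeric array.
#' @param mask 2D integer label array of the same shape.
#' @param params list with `scale_range` (relative, e.g. 0.1 for +/-10%),
#'   `rotate_range_deg`, `translate_range_px`.
#' @param seed RNG seed.
#' @return list with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, params, seed = 1L) {
  set.seed(seed)
  sc <- 1 + stats::runif(1, -1, 1) * (params$scale_range %||% 0)
  th <- stats::runif(1, -1, 1) * (params$rotate_range_deg %||% 0)
  tr <- stats::runif(2, -1, 1) * (params$translate_range_px %||% 0)
  apply_similarity(image, mask, scale = sc, angle_deg = th, translate = tr)
}

#' Apply one similarity transform to an (image, mask) pair
#'
#' Deterministic kernel behind [augment]: scales by `scale`, rotates by
#' `angle_deg` (positive angles turn the +row axis toward the +column axis)
#' and translates by `translate` pixels, all about the image centre. The
#' image is interpolated bilinearly, the mask by nearest neighbour.
#'
#' @param image 2D numeric array.
#' @param mask 2D integer label array of the same shape.
#' @param scale,angle_deg,translate transform parameters.
#' @return list with transformed `image` and `mask`.
#' @export
apply_similarity <- function(image, mask, scale = 1, angle_deg = 0,
                             translate = c(0, 0)) {
  if (!all(dim(image) == dim(mask)))
    cmr_stop("data_error", "image and mask shapes differ")
  th <- angle_deg * pi / 180
  nr <- nrow(image); nc <- ncol(image)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  Ainv <- solve(A)
  grid <- expand.grid(row = 0:(nr - 1L), col = 0:(nc - 1L))
  rel <- cbind(grid$row - ctr[1] - translate[1],
               grid$col - ctr[2] - translate[2])
  src <- rel %*% t(Ainv)
  sr <- src[, 1L] + ctr[1]
  sc2 <- src[, 2L] + ctr[2]
  img2 <- matrix(sample_bilinear(image, sr, sc2), nr, nc)
  msk2 <- matrix(as.integer(sample_nearest(mask, sr, sc2)), nr, nc)
  list(image = img2, mask = msk2)
}

#' Dice overlap coefficient
#'
#' @param a,b label arrays of equal shape.
#' @param label the label to compare (default 1).
#' @return Dice coefficient in \[0, 1\] (1 when both regions are empty).
#' @export
dice <- function(a, b, label = 1L) {
  x <- a == label
  y <- b == label
  denom <- sum(x) + sum(y)
  if (denom == 0) return(1)
  2 * sum(x & y) / denom
}

#' Oracle segmenter backed by phantom ground truth
#'
#' Returns a segmenter function `(plane, phase, image)` producing the exact
#' analytic 3-class mask for any image plane and phase of the phantom —
#' decoupling the geometry, volumetric and statistical stages from CNN
#' training quality. On the planes of the generating study the masks are
#' bit-identical to `truth$masks`. Optional seeded label-noise injection
#' (boundary erosion or dilation of the blood pool) supports robustness
#' tests.
#'
#' @param truth a `phantom_truth`.
#' @param noise_px erosion/dilation radius in pixels (0 = exact masks).
#' @param noise_mode `"none"`, `"erode"` or `"dilate"`.
#' @param seed seed for any randomised noise (reserved; the morphological
#'   modes are deterministic).
#' @return function of class `oracle_segmenter`.
#' @export
oracle_segmenter <- function(truth, noise_px = 0L,
                             noise_mode = c("none", "erode", "dilate"),
                             seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  spec <- truth$spec
  coord_cache <- new.env(parent = emptyenv())
  segfun <- function(plane, phase, image = NULL) {
    if (phase < 1L || phase > spec$n_phases)
      cmr_stop("data_error", sprintf("unknown phase %s", phase))
    key <- paste(c(plane$origin, plane$row_dir, plane$col_dir,
                   plane$n_rows, plane$n_cols), collapse = ",")
    L <- coord_cache[[key]]
    if (is.null(L)) {
      L <- plane_local_coords(plane, spec$pose)
      coord_cache[[key]] <- L
    }
    lab <- rasterize_labels_local(L, truth$inner[phase, ],
                                  truth$outer[phase, ])
    m <- matrix(lab, plane$n_rows, plane$n_cols)
    if (noise_px > 0L && noise_mode != "none") {
      blood <- (m == 1L) * 1
      brush <- EBImage::makeBrush(2L * as.integer(noise_px) + 1L, "diamond")
      blood2 <- if (noise_mode == "erode") {
        EBImage::erode(blood, brush) > 0
      } else {
        EBImage::dilate(blood, brush) > 0
      }
      # eroded-away blood reads as myocardium (boundary under-segmentation);
      # dilation overwrites the adjacent myocardium
      m[blood > 0 & !blood2] <- 2L
      m[blood2] <- 1L
    }
    m
  }
  structure(segfun, class = c("oracle_segmenter", "function"))
}

#' @keywords internal
#' Centre crop/pad a 2D array to a square target size.
#' @noRd
fit_to_size <- function(img, size, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, size, size)
  r_src <- max(1L, (nr - size) %/% 2L + 1L)
  c_src <- max(1L, (nc - size) %/% 2L + 1L)
  r_dst <- max(1L, (size - nr) %/% 2L + 1L)
  c_dst <- max(1L, (size - nc) %/% 2L + 1L)
  h <- min(nr, size); w <- min(nc, size)
  out[r_dst:(r_dst + h - 1L), c_dst:(c_dst + w - 1L)] <-
    img[r_src:(r_src + h - 1L), c_src:(c_src + w - 1L)]
  attr(out, "crop") <- c(r_src = r_src, c_src = c_src, r_dst = r_dst,
                         c_dst = c_dst, h = h, w = w, nr = nr, nc = nc)
  out
}

#' @noRd
unfit_from_size <- function(img, crop, fill = 0L) {
  out <- matrix(fill, crop["nr"], crop["nc"])
  out[crop["r_src"]:(crop["r_src"] + crop["h"] - 1L),
      crop["c_src"]:(crop["c_src"] + crop["w"] - 1L)] <-
    img[crop["r_dst"]:(crop["r_dst"] + crop["h"] - 1L),
        crop["c_dst"]:(crop["c_dst"] + crop["w"] - 1L)]
  out
}

#' Wrap a trained U-net as a study segmenter
#'
#' The image is centre cropped/padded to the network input size, segmented,
#' and the mask mapped back onto the original grid (pixels outside the
#' network field of view are background).
#'
#' @param model a trained `unet_model`.
#' @return segmenter function `(plane, phase, image)`.
#' @export
unet_segmenter <- function(model) {
  size <- model$config$input_size
  segfun <- function(plane, phase, image) {
    x <- fit_to_size(image, size)
    crop <- attr(x, "crop")
    lab <- predict_unet(model, x)
    unfit_from_size(lab, crop)
  }
  structure(segfun, class = c("unet_segmenter", "function"))
}

#' Segment every slice of a study
#'
#' Runs a segmenter over the short-axis stack for all phases. The blood pool
#' is segmented in every phase; when `myocardium_at_ed_only` is set (the
#' default, matching a dedicated diastole-only myocardium model),
#' end-diastole is first identified as the phase with the largest untrimmed
#' blood volume and myocardium labels are retained only in that phase.
#'
#' @param study a `cine_study` (typically with normalised planes).
#' @param segmenter function `(plane, phase, image)` returning a label mask,
#'   e.g. from [oracle_segmenter] or [unet_segmenter].
#' @param myocardium_at_ed_only keep myocardium labels only at ED.
#' @return list with `masks` (list over slices of lists over phases),
#'   `blood_ml_untrimmed` (per-phase), `ed_index`, `es_index`.
#' @export
segment_study <- function(study, segmenter, myocardium_at_ed_only = TRUE) {
  n_sl <- length(study$sax$planes)
  n_ph <- study$n_phases
  masks <- lapply(seq_len(n_sl), function(k) vector("list", n_ph))
  for (k in seq_len(n_sl)) {
    pl <- study$sax$planes[[k]]
    for (p in seq_len(n_ph)) {
      px <- study$sax$pixels
      img <- if (is.null(px)) NULL
      else if (is.list(px)) px[[k]][[p]]
      else px[, , k, p]
      masks[[k]][[p]] <- segmenter(pl, p, img)
    }
  }
  blood <- vapply(seq_len(n_ph), function(p) {
    sum(vapply(seq_len(n_sl), function(k) {
      slice_volume(masks[[k]][[p]], study$sax$planes[[k]], label = 1L)
    }, numeric(1)))
  }, numeric(1))
  ph <- select_phases(blood)
  if (myocardium_at_ed_only) {
    for (k in seq_len(n_sl)) for (p in seq_len(n_ph)) {
      if (p != ph$ed_index) {
        m <- masks[[k]][[p]]
        m[m == 2L] <- 0L
        masks[[k]][[p]] <- m
      }
    }
  }
  list(masks = masks, blood_ml_untrimmed = blood,
       ed_index = ph$ed_index, es_index = ph$es_index)
}
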