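test_that("pixel_to_patient is the DICOM affine map", {
  pl <- image_plane(c(10, 20, 30), c(1, 0, 0), c(0, 1, 0), 1, 1, 8, 64, 64)
  expect_equal(pixel_to_patient(pl, 0, 0), c(10, 20, 30))

  pl2 <- image_plane(c(10, 20, 30), c(1, 0, 0), c(0, 1, 0), 2, 3, 8, 64, 64)
  expect_equal(pixel_to_patient(pl2, 4, 5), c(18, 35, 30))

  # against a 4x4 homogeneous-matrix oracle on oblique planes
  for (seed in 1:5) {
    pl3 <- random_plane(seed)
    M <- cbind(pl3$row_dir * pl3$row_spacing, pl3$col_dir * pl3$col_spacing,
               plane_normal(pl3), pl3$origin)
    M <- rbind(M, c(0, 0, 0, 1))
    rc <- runif(2, -5, 40)
    expected <- (M %*% c(rc[1], rc[2], 0, 1))[1:3]
    expect_equal(pixel_to_patient(pl3, rc[1], rc[2]), as.numeric(expected),
                 tolerance = 1e-9)
  }
})

test_that("patient_to_pixel inverts pixel_to_patient and signs out-of-plane", {
  pl <- random_plane(11)
  px <- patient_to_pixel(pl, pixel_to_patient(pl, 7, 11))
  expect_equal(px$row, 7, tolerance = 1e-9)
  expect_equal(px$col, 11, tolerance = 1e-9)
  expect_equal(px$out_of_plane, 0, tolerance = 1e-9)

  p <- pixel_to_patient(pl, 3, 4) + 5 * plane_normal(pl)
  expect_equal(patient_to_pixel(pl, p)$out_of_plane, 5, tolerance = 1e-9)
  p <- pixel_to_patient(pl, 3, 4) - 5 * plane_normal(pl)
  expect_equal(patient_to_pixel(pl, p)$out_of_plane, -5, tolerance = 1e-9)

  set.seed(42)
  pts <- matrix(rnorm(3000, 0, 50), ncol = 3)
  px <- patient_to_pixel(pl, pts)
  rec <- pixel_to_patient(pl, px$row, px$col) +
    outer(px$out_of_plane, plane_normal(pl))
  expect_lt(max(abs(rec - pts)), 1e-9)
})

test_that("image_plane validates its invariants", {
  expect_error(image_plane(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), 1, 1, 8, 4, 4),
               class = "domain_error")
  expect_error(image_plane(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), 1, 1, 8, 4, 4),
               class = "domain_error")
  expect_error(image_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), -1, 1, 8, 4, 4),
               class = "domain_error")
})

test_that("plane_intersection_line lies in both planes and is symmetric", {
  z0 <- image_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 1, 1, 8, 4, 4)
  y0 <- image_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), 1, 1, 8, 4, 4)
  ln <- plane_intersection_line(z0, y0)
  expect_equal(abs(ln$direction), c(1, 0, 0))
  expect_equal(ln$point[2:3], c(0, 0), tolerance = 1e-9)

  par1 <- image_plane(c(0, 0, 8), c(1, 0, 0), c(0, 1, 0), 1, 1, 8, 4, 4)
  expect_error(plane_intersection_line(z0, par1),
               class = "parallel_planes_error")

  dist_to_plane <- function(p, pl) {
    abs(sum((p - pl$origin) * plane_normal(pl)))
  }
  for (seed in 1:5) {
    a <- random_plane(seed)
    b <- random_plane(seed + 50)
    ln <- plane_intersection_line(a, b)
    for (p in list(ln$point, ln$point + 100 * ln$direction)) {
      expect_lt(dist_to_plane(p, a), 1e-6)
      expect_lt(dist_to_plane(p, b), 1e-6)
    }
    ln2 <- plane_intersection_line(b, a)
    # same point set: point of one lies on the other, directions parallel
    expect_equal(abs(sum(ln$direction * ln2$direction)), 1, tolerance = 1e-9)
    expect_lt(
      sqrt(sum(cross_prod_test(ln2$point - ln$point, ln$direction)^2)),
      1e-6)
  }
})

test_that("three_plane_point solves the three-plane system", {
  px <- image_plane(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), 1, 1, 8, 4, 4)
  py <- image_plane(c(0, 2, 0), c(0, 0, 1), c(1, 0, 0), 1, 1, 8, 4, 4)
  pz <- image_plane(c(0, 0, 3), c(1, 0, 0), c(0, 1, 0), 1, 1, 8, 4, 4)
  expect_equal(three_plane_point(px, py, pz), c(1, 2, 3), tolerance = 1e-9)
  expect_error(three_plane_point(px, py,
                                 image_plane(c(5, 0, 0), c(0, 1, 0),
                                             c(0, 0, 1), 1, 1, 8, 4, 4)),
               class = "degenerate_geometry_error")

  g <- small_phantom()
  n_sl <- length(g$study$sax$planes)
  mid <- g$study$sax$planes[[n_sl %/% 2L + 1L]]
  pt <- three_plane_point(mid, g$study$ch2$plane, g$study$ch4$plane)
  expect_lt(sqrt(sum((pt - g$truth$axis_anchor)^2)), 1e-6)
})

test_that("normalisation maps the anchor to the origin and the SAx/2Ch line to y", {
  g <- small_phantom()
  st <- g$study
  n_sl <- length(st$sax$planes)
  mid <- st$sax$planes[[n_sl %/% 2L + 1L]]
  tr <- build_normalization(mid, st$ch2$plane, st$ch4$plane,
                            apex_reference = g$truth$apex_point)
  expect_equal(crossprod(tr$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)

  anchor <- three_plane_point(mid, st$ch2$plane, st$ch4$plane)
  expect_lt(max(abs(apply_transform(tr, anchor))), 1e-9)

  ln <- plane_intersection_line(mid, st$ch2$plane)
  d_canon <- as.numeric(tr$rotation %*% ln$direction)
  expect_lt(acos(pmin(1, abs(d_canon[2]))), 1e-9)

  ns_canon <- as.numeric(tr$rotation %*% plane_normal(mid))
  expect_lt(acos(pmin(1, abs(ns_canon[3]))), 1e-9)
  # apex reference maps to negative z
  expect_lt(apply_transform(tr, g$truth$apex_point)[3], 0)
})

test_that("normalisation of an already-normalised study is the identity", {
  g <- small_phantom()
  norm <- normalize_study(g$study)
  st <- norm$study
  n_sl <- length(st$sax$planes)
  mid <- st$sax$planes[[n_sl %/% 2L + 1L]]
  apex_pl <- st$sax$planes[[1L]]
  apex_ref <- pixel_to_patient(apex_pl, (apex_pl$n_rows - 1) / 2,
                               (apex_pl$n_cols - 1) / 2)
  tr2 <- build_normalization(mid, st$ch2$plane, st$ch4$plane,
                             apex_reference = apex_ref)
  expect_equal(tr2$rotation, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(tr2$translation)), 1e-9)
})

test_that("normalisation is invariant to global rigid motion of the study", {
  g <- small_phantom()
  st <- g$study
  n_sl <- length(st$sax$planes)
  move <- rigid_pose(37, c(1, -2, 3), c(12, -40, 25))
  move_plane <- function(pl) transform_plane(pl, move$rotation,
                                             move$translation)
  mv_pt <- function(p) as.numeric(move$rotation %*% p) + move$translation

  mid <- st$sax$planes[[n_sl %/% 2L + 1L]]
  tr1 <- build_normalization(mid, st$ch2$plane, st$ch4$plane,
                             apex_reference = g$truth$apex_point)
  tr2 <- build_normalization(move_plane(mid), move_plane(st$ch2$plane),
                             move_plane(st$ch4$plane),
                             apex_reference = mv_pt(g$truth$apex_point))
  # any anatomical point has the same canonical coordinates in both frames
  for (p in list(g$truth$apex_point, g$truth$base_point,
                 g$truth$mv_points_2ch[1, 1, ])) {
    expect_equal(apply_transform(tr2, mv_pt(p)), apply_transform(tr1, p),
                 tolerance = 1e-6)
  }
})
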