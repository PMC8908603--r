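test_that("truncated ellipsoid volume matches closed forms and Monte Carlo", {
  expect_equal(analytic_truncated_ellipsoid_volume(10, 10, 10, 0),
               4 / 3 * pi, tolerance = 1e-12)
  expect_equal(analytic_truncated_ellipsoid_volume(10, 10, 10, 10),
               2 / 3 * pi, tolerance = 1e-12)
  expect_error(analytic_truncated_ellipsoid_volume(10, 10, 10, 25),
               class = "domain_error")
  expect_error(analytic_truncated_ellipsoid_volume(-1, 10, 10, 0),
               class = "domain_error")

  # Monte-Carlo oracle: uniform points in the bounding box
  a <- 30; b <- 25; c <- 45; h <- 13.5
  set.seed(99)
  n <- 1e7
  x <- runif(n, -a, a); y <- runif(n, -b, b); z <- runif(n, -c, c)
  inside <- (x / a)^2 + (y / b)^2 + (z / c)^2 <= 1 & z <= c - h
  mc <- mean(inside) * 8 * a * b * c / 1000
  an <- analytic_truncated_ellipsoid_volume(a, b, c, h)
  expect_lt(abs(mc - an) / an, 0.001)
})

test_that("generation is deterministic and hits the EF target exactly", {
  sp <- small_spec()
  g1 <- generate_study(sp)
  g2 <- generate_study(sp)
  expect_identical(g1$study, g2$study)
  expect_identical(g1$truth$masks, g2$truth$masks)

  expect_equal(g1$truth$ef_pct, 60, tolerance = 1e-6)
  g3 <- generate_study(small_spec(ef_target = 0.45))
  expect_equal(g3$truth$ef_pct, 45, tolerance = 1e-6)
  # EF identity holds exactly
  tr <- g1$truth
  expect_equal(tr$ef_pct, 100 * (tr$edv_ml - tr$esv_ml) / tr$edv_ml,
               tolerance = 1e-9)
})

test_that("voxelised truth masks reproduce the analytic EDV", {
  # 1 mm grid, untrimmed full-ellipsoid blood count vs closed form
  sp <- phantom_spec(pixel_spacing = 1, sax_grid = 144L, sax_spacing = 2,
                     n_sax_slices = 60L, n_phases = 2L, noise_sd = 0)
  g <- generate_study(sp)
  vox <- sum(g$truth$masks$sax[, , , 1L] == 1L) * 1 * 1 * 2 / 1000
  full <- analytic_truncated_ellipsoid_volume(
    sp$semi_axes_ed[1], sp$semi_axes_ed[2], sp$semi_axes_ed[3], 0)
  expect_lt(abs(vox - full) / full, 0.015)
})

test_that("phantom truth satisfies its geometric invariants", {
  g <- small_phantom()
  tr <- g$truth
  # annulus points lie exactly on the per-phase valve plane
  for (p in seq_len(g$study$n_phases)) {
    mv <- tr$mv_plane[[p]]
    pts <- rbind(tr$mv_points_2ch[p, , ], tr$mv_points_4ch[p, , ])
    expect_lt(max(abs(mv_signed_distance(mv, pts))), 1e-9)
    expect_equal(sqrt(sum(mv$normal^2)), 1, tolerance = 1e-9)
  }
  # labels partition every pixel
  expect_true(all(tr$masks$sax %in% 0:2))
  # blood pool is brighter than myocardium, brighter than background
  g0 <- generate_study(small_spec(noise_sd = 0))
  px <- g0$study$sax$pixels[, , , 1L]
  lab <- g0$truth$masks$sax[, , , 1L]
  expect_true(min(px[lab == 1L]) > max(px[lab == 2L]))
  expect_true(min(px[lab == 2L]) > max(px[lab == 0L]))
})

test_that("analytic EF is invariant to pose, pixel size and noise seed", {
  ef <- vapply(list(
    small_spec(seed = 7L),
    small_spec(seed = 8L, noise_sd = 0.1),
    small_spec(pose = rigid_pose(80, c(0, 1, 1), c(50, 0, -20))),
    small_spec(pixel_spacing = 3)
  ), function(sp) generate_study(sp)$truth$ef_pct, numeric(1))
  expect_equal(ef, rep(60, 4), tolerance = 1e-9)
})

test_that("myocardial shell volume is conserved across phases", {
  g <- small_phantom()
  tr <- g$truth
  spec <- tr$spec
  f <- spec$truncation_fraction
  for (p in c(2L, 4L)) {
    inner <- tr$inner[p, ]
    outer <- tr$outer[p, ]
    zc <- f * inner[3]
    wall <- analytic_truncated_ellipsoid_volume(outer[1], outer[2], outer[3],
                                                outer[3] - zc) -
      analytic_truncated_ellipsoid_volume(inner[1], inner[2], inner[3],
                                          inner[3] - zc)
    expect_equal(wall, tr$myo_volume_ml_ed, tolerance = 1e-6)
  }
})

test_that("rescan with zero perturbation reproduces the study bit for bit", {
  g <- small_phantom()
  r <- rescan(g$study, g$truth,
              list(translation = 0, rotation_deg = 0, slice_shift = 0),
              seed = g$truth$spec$seed)
  expect_identical(r$study, g$study)
  expect_identical(r$truth$masks, g$truth$masks)
})

test_that("rescan re-prescribes planes but keeps the analytic truth", {
  g <- small_phantom()
  r <- rescan(g$study, g$truth,
              list(translation = 2, rotation_deg = 3, slice_shift = 3),
              seed = 5L)
  expect_identical(r$truth$edv_ml, g$truth$edv_ml)
  expect_identical(r$truth$esv_ml, g$truth$esv_ml)
  expect_identical(r$truth$lvm_g, g$truth$lvm_g)
  expect_false(identical(r$study$sax$planes[[1L]]$origin,
                         g$study$sax$planes[[1L]]$origin))
  # deterministic given the seed
  r2 <- rescan(g$study, g$truth,
               list(translation = 2, rotation_deg = 3, slice_shift = 3),
               seed = 5L)
  expect_identical(r$study, r2$study)
})

test_that("random subject specs are seeded and span the stated ranges", {
  s1 <- random_phantom_spec(42)
  s2 <- random_phantom_spec(42)
  expect_identical(s1, s2)
  s3 <- random_phantom_spec(43)
  expect_false(identical(s1$semi_axes_ed, s3$semi_axes_ed))
  specs <- lapply(1:10, random_phantom_spec)
  ax <- t(vapply(specs, `[[`, numeric(3), "semi_axes_ed"))
  expect_true(all(ax[, 1:2] >= 20 & ax[, 1:2] <= 28))
  expect_true(all(ax[, 3] >= 40 & ax[, 3] <= 50))
  ef <- vapply(specs, `[[`, numeric(1), "ef_target")
  expect_true(all(ef >= 0.45 & ef <= 0.7))
})

test_that("stack specification errors when slices cannot cover the ventricle", {
  expect_error(generate_study(small_spec(n_sax_slices = 5L)),
               class = "spec_error")
})

test_that("breath-hold offset moves only the long-axis plane headers", {
  g <- small_phantom()
  st2 <- breathhold_offset(g$study, c(0, 0, 0))
  expect_identical(st2, g$study)
  off <- c(3, -4, 5)
  st3 <- breathhold_offset(g$study, off)
  expect_equal(st3$ch2$plane$origin, g$study$ch2$plane$origin + off)
  expect_equal(st3$ch4$plane$origin, g$study$ch4$plane$origin + off)
  expect_identical(st3$sax, g$study$sax)
  expect_identical(st3$ch2$pixels, g$study$ch2$pixels)
  expect_identical(st3$ch2$mv_px, g$study$ch2$mv_px)
})
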