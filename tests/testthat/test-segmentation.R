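tiny_config <- function(...) {
  args <- list(input_size = 16L, depth = 2L, base_filters = 3L,
               dilations = c(1L, 2L), learning_rate = 1e-3,
               epochs = 1L, batch_size = 2L, augmentation = NULL,
               seed = 42L)
  do.call(segmenter_config, utils::modifyList(args, list(...)))
}

test_that("augmentation transforms image and mask identically", {
  set.seed(2)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(sample(0:2, 32 * 32, TRUE), 32, 32)

  a0 <- augment(img, mask, list(scale_range = 0, rotate_range_deg = 0,
                                translate_range_px = 0), seed = 1)
  expect_equal(a0$image, img)
  expect_identical(a0$mask, mask)

  pars <- list(scale_range = 0.15, rotate_range_deg = 30,
               translate_range_px = 5)
  a1 <- augment(img, mask, pars, seed = 7)
  a2 <- augment(img, mask, pars, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% 0:2))
  expect_true(all(a1$image >= 0 & a1$image <= max(img)))

  # image and mask stay registered: painting a spatially structured label
  # field as intensities and transforming must agree with the transformed
  # mask wherever the interpolated value is unambiguous
  blocky <- outer(0:31, 0:31, function(i, j) ((i %/% 8) + (j %/% 8)) %% 3L)
  painted <- (blocky == 1) * 1.0 + (blocky == 2) * 0.5
  ap <- augment(painted, blocky, pars, seed = 3)
  implied <- matrix(0L, 32, 32)
  implied[abs(ap$image - 1) < 0.05] <- 1L
  implied[abs(ap$image - 0.5) < 0.05] <- 2L
  certain <- abs(ap$image) < 0.05 | abs(ap$image - 0.5) < 0.05 |
    abs(ap$image - 1) < 0.05
  expect_gt(mean(certain), 0.5)
  expect_gt(mean((implied == ap$mask)[certain]), 0.95)
})

test_that("a quarter-turn similarity matches the array rotation oracle", {
  set.seed(4)
  img <- matrix(runif(16 * 16), 16, 16)
  mask <- matrix(sample(0:2, 256, TRUE), 16, 16)
  rot90_oracle <- function(m) t(m[, ncol(m):1])
  a <- apply_similarity(img, mask, scale = 1, angle_deg = 90)
  expect_equal(a$image, rot90_oracle(img), tolerance = 1e-12)
  expect_identical(a$mask, rot90_oracle(mask))
  # four quarter turns are the identity
  b <- a
  for (i in 1:3) b <- apply_similarity(b$image, b$mask, angle_deg = 90)
  expect_equal(b$image, img, tolerance = 1e-12)
  expect_identical(b$mask, mask)
})

test_that("build_unet validates configuration and reports parameters", {
  expect_error(segmenter_config(input_size = 100L, depth = 3L),
               class = "config_error")
  expect_error(segmenter_config(learning_rate = 0), class = "config_error")
  m <- build_unet(tiny_config())
  expect_s3_class(m, "unet_model")
  expect_gt(m$n_params, 1000)
})

test_that("softmax output is a probability field over three classes", {
  m <- build_unet(tiny_config())
  probs <- predict_unet_probs(m, matrix(0, 16, 16))
  expect_equal(dim(probs), c(16L, 16L, 3L))
  expect_lt(max(abs(apply(probs, c(1, 2), sum) - 1)), 1e-5)

  set.seed(1)
  lab <- predict_unet(m, matrix(runif(256), 16, 16))
  expect_true(all(lab %in% 0:2))
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_config()
  model <- build_unet(cfg)
  set.seed(7)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  y <- array(sample(1:3, 16 * 16 * 2, TRUE), c(16, 16, 2))
  fwd <- unet_fwd(model, x, train = TRUE)
  bwd <- unet_bwd(model, fwd, y)
  eps <- 1e-5
  loss_at <- function(m) unet_loss(unet_fwd(m, x, train = TRUE), y)
  set.seed(1)
  for (name in c("enc1_1", "bott2", "dec1_2", "final")) {
    # conv biases feeding batch norm are absorbed (gradient exactly 0);
    # check weights and batch-norm affine parameters
    fields <- intersect(names(bwd$grads[[name]]), c("w", "gamma", "beta"))
    for (field in fields) {
      par <- model$params[[name]][[field]]
      for (trial in 1:3) {
        i <- sample(length(par), 1)
        m2 <- model
        m2$params[[name]][[field]][i] <- par[i] + eps
        m3 <- model
        m3$params[[name]][[field]][i] <- par[i] - eps
        num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
        ana <- bwd$grads[[name]][[field]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
  }
})

test_that("one Adam step decreases the loss on a single pair", {
  cfg <- tiny_config()
  model <- build_unet(cfg)
  set.seed(3)
  x <- array(runif(16 * 16), c(16, 16, 1))
  y <- array(sample(1:3, 256, TRUE, prob = c(0.6, 0.3, 0.1)), c(16, 16, 1))
  fwd <- unet_fwd(model, x, train = TRUE)
  bwd <- unet_bwd(model, fwd, y)
  upd <- adam_step(model$params, bwd$grads, list(t = 0L, m = list(),
                                                 v = list()),
                   lr = cfg$learning_rate)
  model2 <- model
  model2$params <- upd$params
  loss2 <- unet_loss(unet_fwd(model2, x, train = TRUE), y)
  expect_lt(loss2, bwd$loss)
})

test_that("training collapses to the majority class on constant labels", {
  set.seed(5)
  imgs <- array(runif(16 * 16 * 8), c(16, 16, 8))
  msks <- array(0L, c(16, 16, 8))
  cfg <- tiny_config(epochs = 40L, batch_size = 2L, learning_rate = 1e-2)
  model <- train_segmenter(imgs, msks, cfg)
  pred <- predict_unet(model, imgs)
  expect_true(all(pred == 0L))
  expect_lt(model$loss_trace[length(model$loss_trace)], model$loss_trace[1])
})

test_that("the oracle segmenter reproduces truth masks and injects noise", {
  g <- small_phantom()
  seg <- oracle_segmenter(g$truth)
  grid <- g$truth$spec$sax_grid
  for (k in c(1L, 7L)) {
    m <- seg(g$study$sax$planes[[k]], 1L)
    expect_identical(m, matrix(g$truth$masks$sax[, , k, 1L], grid, grid))
  }
  expect_error(seg(g$study$sax$planes[[1L]], 99L), class = "data_error")

  seg_e <- oracle_segmenter(g$truth, noise_px = 1L, noise_mode = "erode")
  seg_d <- oracle_segmenter(g$truth, noise_px = 1L, noise_mode = "dilate")
  pl <- g$study$sax$planes[[7L]]
  a0 <- sum(seg(pl, 1L) == 1L)
  expect_lt(sum(seg_e(pl, 1L) == 1L), a0)
  expect_gt(sum(seg_d(pl, 1L) == 1L), a0)
})

test_that("segment_study keeps myocardium only at end-diastole when asked", {
  g <- small_phantom()
  seg <- segment_study(g$study, oracle_segmenter(g$truth),
                       myocardium_at_ed_only = TRUE)
  for (k in seq_along(g$study$sax$planes)) {
    for (p in seq_len(g$study$n_phases)) {
      has_myo <- any(seg$masks[[k]][[p]] == 2L)
      if (p != seg$ed_index) expect_false(has_myo)
    }
  }
  expect_true(any(vapply(seq_along(g$study$sax$planes), function(k)
    any(seg$masks[[k]][[seg$ed_index]] == 2L), logical(1))))

  seg_all <- segment_study(g$study, oracle_segmenter(g$truth),
                           myocardium_at_ed_only = FALSE)
  expect_true(any(seg_all$masks[[7L]][[3L]] == 2L))
})
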