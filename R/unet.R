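# Small fully-convolutional U-net, implemented directly on BLAS matrix
# products (im2col). Feature maps are carried as matrices m[H*W*N, C] with
# rows ordered (h, w, n) h-fastest, plus the spatial dims — convolutions,
# batch norm and the classifier head are then plain matrix ops, and only
# pooling/upsampling touch the 4D view.

fm <- function(m, H, W, N) list(m = m, H = H, W = W, N = N)
fm_array <- function(f) array(f$m, c(f$H, f$W, f$N, ncol(f$m)))
array_fm <- function(a) {
  d <- dim(a)
  fm(`dim<-`(a, c(d[1] * d[2] * d[3], d[4])), d[1], d[2], d[3])
}

conv_fwd <- function(f, wmat, b, dilation = 1L) {
  H <- f$H; W <- f$W; N <- f$N
  Cin <- ncol(f$m)
  d <- dilation
  arr <- fm_array(f)
  arrp <- array(0, c(H + 2 * d, W + 2 * d, N, Cin))
  arrp[d + seq_len(H), d + seq_len(W), , ] <- arr
  X <- matrix(0, H * W * N, 9L * Cin)
  kk <- 0L
  for (j in 0:2) for (i in 0:2) {
    sub <- arrp[i * d + seq_len(H), j * d + seq_len(W), , , drop = FALSE]
    X[, kk * Cin + seq_len(Cin)] <- `dim<-`(sub, c(H * W * N, Cin))
    kk <- kk + 1L
  }
  Y <- X %*% wmat
  Y <- sweep(Y, 2L, b, "+")
  list(out = fm(Y, H, W, N), X = X, Cin = Cin, dilation = d)
}

conv_bwd <- function(cache, wmat, dout, H, W, N) {
  dW <- crossprod(cache$X, dout)
  db <- colSums(dout)
  dX <- dout %*% t(wmat)
  Cin <- cache$Cin
  d <- cache$dilation
  dxp <- array(0, c(H + 2 * d, W + 2 * d, N, Cin))
  kk <- 0L
  for (j in 0:2) for (i in 0:2) {
    blk <- array(dX[, kk * Cin + seq_len(Cin)], c(H, W, N, Cin))
    ri <- i * d + seq_len(H)
    cj <- j * d + seq_len(W)
    dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] + blk
    kk <- kk + 1L
  }
  dx <- dxp[d + seq_len(H), d + seq_len(W), , , drop = FALSE]
  list(dW = dW, db = db, dx = `dim<-`(dx, c(H * W * N, Cin)))
}

bn_fwd <- function(m, gamma, beta, running, train, momentum = 0.1,
                   eps = 1e-5) {
  if (train) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu)
    v <- colMeans(xc^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(m, 2L, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, xhat = xhat, inv = inv, running = running)
}

bn_bwd <- function(cache, gamma, dy) {
  R <- nrow(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2L, m1) - sweep(cache$xhat, 2L, m2, "*")
  dx <- sweep(dx, 2L, cache$inv, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(f) {
  arr <- fm_array(f)
  H <- f$H; W <- f$W
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  s <- list(arr[i1, j1, , , drop = FALSE], arr[i2, j1, , , drop = FALSE],
            arr[i1, j2, , , drop = FALSE], arr[i2, j2, , , drop = FALSE])
  mx <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  code <- ifelse(s[[1]] == mx, 1L,
                 ifelse(s[[2]] == mx, 2L, ifelse(s[[3]] == mx, 3L, 4L)))
  list(out = array_fm(mx), code = code, H = H, W = W)
}

pool_bwd <- function(cache, dout_fm) {
  darr4 <- fm_array(dout_fm)
  H <- cache$H; W <- cache$W
  dims <- dim(darr4)
  darr <- array(0, c(H, W, dims[3], dims[4]))
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  darr[i1, j1, , ] <- darr4 * (cache$code == 1L)
  darr[i2, j1, , ] <- darr[i2, j1, , , drop = FALSE] +
    darr4 * (cache$code == 2L)
  darr[i1, j2, , ] <- darr[i1, j2, , , drop = FALSE] +
    darr4 * (cache$code == 3L)
  darr[i2, j2, , ] <- darr[i2, j2, , , drop = FALSE] +
    darr4 * (cache$code == 4L)
  array_fm(darr)
}

upsample_fwd <- function(f) {
  arr <- fm_array(f)
  arr2 <- arr[rep(seq_len(f$H), each = 2L), rep(seq_len(f$W), each = 2L), , ,
              drop = FALSE]
  array_fm(arr2)
}

upsample_bwd <- function(dout_fm) {
  darr <- fm_array(dout_fm)
  H2 <- dout_fm$H; W2 <- dout_fm$W
  i1 <- seq(1L, H2, 2L); i2 <- seq(2L, H2, 2L)
  j1 <- seq(1L, W2, 2L); j2 <- seq(2L, W2, 2L)
  d <- darr[i1, j1, , , drop = FALSE] + darr[i2, j1, , , drop = FALSE] +
    darr[i1, j2, , , drop = FALSE] + darr[i2, j2, , , drop = FALSE]
  array_fm(d)
}

#' Segmenter configuration
#'
#' Hyper-parameters of the U-net segmentation models. The optimiser is Adam
#' with learning rate 1e-4 and no decay by default; `augmentation` gives the
#' maximum magnitudes of the random scaling / rotation / translation applied
#' during training. `input_size` must be divisible by `2^depth`.
#'
#' @param input_size square input size in pixels (default 192).
#' @param n_classes output channels (3: background / blood pool / myocardium).
#' @param depth number of encoder pooling stages.
#' @param base_filters filters in the first encoder block (doubled per stage).
#' @param dilations dilation rates of the bottleneck (Atrous) convolutions.
#' @param learning_rate,lr_decay Adam learning rate and per-epoch decay.
#' @param epochs,batch_size training schedule.
#' @param augmentation list: `scale_range` (relative), `rotate_range_deg`,
#'   `translate_range_px`.
#' @param seed RNG seed for initialisation, shuffling and augmentation.
#' @return object of class `segmenter_config`.
#' @export
segmenter_config <- function(input_size = 192L, n_classes = 3L, depth = 4L,
                             base_filters = 32L, dilations = c(1L, 2L, 4L),
                             learning_rate = 1e-4, lr_decay = 0,
                             epochs = 20L, batch_size = 8L,
                             augmentation = list(scale_range = 0.1,
                                                 rotate_range_deg = 15,
                                                 translate_range_px = 8),
                             seed = 1L) {
  if (learning_rate <= 0) cmr_stop("config_error", "learning rate must be > 0")
  if (input_size %% (2^depth) != 0)
    cmr_stop("config_error", "input_size must be divisible by 2^depth")
  structure(list(
    input_size = as.integer(input_size), n_classes = as.integer(n_classes),
    depth = as.integer(depth), base_filters = as.integer(base_filters),
    dilations = as.integer(dilations), learning_rate = learning_rate,
    lr_decay = lr_decay, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), augmentation = augmentation,
    seed = as.integer(seed)
  ), class = "segmenter_config")
}

#' Build a U-net model
#'
#' Encoder-decoder with skip connections: `depth` encoder stages of two
#' 3x3-convolution + batch-normalisation + ReLU blocks followed by 2x2 max
#' pooling, a bottleneck chain of dilated (Atrous) 3x3 convolutions, and a
#' mirrored decoder using nearest-neighbour upsampling and skip
#' concatenation, ending in a 1x1 convolution with softmax over the class
#' channels. Weights use He initialisation, seeded by `config$seed`.
#'
#' @param config a [segmenter_config].
#' @return object of class `unet_model`; `$n_params` reports the parameter
#'   count.
#' @export
build_unet <- function(config) {
  if (!inherits(config, "segmenter_config"))
    config <- do.call(segmenter_config, config)
  set.seed(config$seed)
  D <- config$depth
  filt <- config$base_filters * 2^(0:D)
  params <- list()
  mk_conv <- function(cin, cout) {
    fan_in <- 9 * cin
    list(w = matrix(stats::rnorm(9 * cin * cout, 0, sqrt(2 / fan_in)),
                    9 * cin, cout),
         b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
         run = list(mean = numeric(cout), var = rep(1, cout)))
  }
  for (l in seq_len(D)) {
    cin <- if (l == 1L) 1L else filt[l - 1L]
    params[[paste0("enc", l, "_1")]] <- mk_conv(cin, filt[l])
    params[[paste0("enc", l, "_2")]] <- mk_conv(filt[l], filt[l])
  }
  for (i in seq_along(config$dilations)) {
    cin <- if (i == 1L) filt[D] else filt[D + 1L]
    params[[paste0("bott", i)]] <- mk_conv(cin, filt[D + 1L])
  }
  for (l in rev(seq_len(D))) {
    up_c <- if (l == D) filt[D + 1L] else filt[l + 1L]
    params[[paste0("dec", l, "_1")]] <- mk_conv(up_c + filt[l], filt[l])
    params[[paste0("dec", l, "_2")]] <- mk_conv(filt[l], filt[l])
  }
  params[["final"]] <- list(
    w = matrix(stats::rnorm(filt[1] * config$n_classes, 0,
                            sqrt(2 / filt[1])), filt[1], config$n_classes),
    b = numeric(config$n_classes))
  n_params <- sum(vapply(params, function(p) {
    length(p$w) + length(p$b) + length(p$gamma %||% numeric(0)) +
      length(p$beta %||% numeric(0))
  }, numeric(1)))
  structure(list(params = params, config = config, n_params = n_params),
            class = "unet_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
#' Forward pass. x: array [H, W, N] (grayscale batch). Returns class
#' probabilities and, when `train`, the caches needed for backprop.
unet_fwd <- function(model, x, train = FALSE) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  H <- dim(x)[1]; W <- dim(x)[2]; N <- dim(x)[3]
  cfg <- model$config
  D <- cfg$depth
  cur <- fm(matrix(as.numeric(x), H * W * N, 1L), H, W, N)
  caches <- list()

  run_block <- function(name, cur, dilation = 1L) {
    p <- model$params[[name]]
    cv <- conv_fwd(cur, p$w, p$b, dilation)
    bn <- bn_fwd(cv$out$m, p$gamma, p$beta, p$run, train)
    if (train) model$params[[name]]$run <<- bn$running
    relu <- pmax(bn$y, 0)
    caches[[name]] <<- list(conv = cv, bn = bn, relu_in = bn$y,
                            H = cur$H, W = cur$W, N = cur$N)
    fm(relu, cv$out$H, cv$out$W, cv$out$N)
  }

  skips <- list()
  for (l in seq_len(D)) {
    cur <- run_block(paste0("enc", l, "_1"), cur)
    cur <- run_block(paste0("enc", l, "_2"), cur)
    skips[[l]] <- cur
    pc <- pool_fwd(cur)
    caches[[paste0("pool", l)]] <- pc
    cur <- pc$out
  }
  for (i in seq_along(cfg$dilations)) {
    cur <- run_block(paste0("bott", i), cur, dilation = cfg$dilations[i])
  }
  for (l in rev(seq_len(D))) {
    cur <- upsample_fwd(cur)
    caches[[paste0("upc", l)]] <- ncol(cur$m)   # channels before concat
    cur <- fm(cbind(cur$m, skips[[l]]$m), cur$H, cur$W, cur$N)
    cur <- run_block(paste0("dec", l, "_1"), cur)
    cur <- run_block(paste0("dec", l, "_2"), cur)
  }
  pf <- model$params[["final"]]
  logits <- sweep(cur$m %*% pf$w, 2L, pf$b, "+")
  pm <- exp(logits - apply(logits, 1L, max))
  probs <- pm / rowSums(pm)
  list(probs = probs, logits = logits, H = H, W = W, N = N,
       caches = if (train) caches else NULL,
       final_in = if (train) cur$m else NULL,
       model = model)
}

#' @noRd
#' Softmax cross-entropy loss of a forward pass against integer labels
#' (array [H, W, N], values 1..K).
unet_loss <- function(fwd, labels) {
  R <- nrow(fwd$probs)
  lab <- as.integer(labels)
  if (length(lab) != R) cmr_stop("data_error", "label/image shape mismatch")
  -mean(log(pmax(fwd$probs[cbind(seq_len(R), lab)], 1e-12)))
}

#' @noRd
#' Backward pass from softmax cross-entropy. Returns the loss and gradients
#' named like the parameter list. Order: the decoder runs levels D..1 in the
#' forward pass, so the backward walks decoder levels 1..D (banking each
#' skip gradient), then the bottleneck, then the encoder levels D..1 adding
#' the banked skip gradients.
unet_bwd <- function(model, fwd, labels) {
  cfg <- model$config
  D <- cfg$depth
  R <- nrow(fwd$probs)
  lab <- as.integer(labels)
  if (length(lab) != R) cmr_stop("data_error", "label/image shape mismatch")
  pt <- fwd$probs[cbind(seq_len(R), lab)]
  loss <- -mean(log(pmax(pt, 1e-12)))
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(R), lab)] <- dlogits[cbind(seq_len(R), lab)] - 1
  dlogits <- dlogits / R

  grads <- list()
  caches <- fwd$caches
  bwd_block <- function(name, dcur) {
    ca <- caches[[name]]
    p <- model$params[[name]]
    drelu <- dcur * (ca$relu_in > 0)
    bb <- bn_bwd(ca$bn, p$gamma, drelu)
    cb <- conv_bwd(ca$conv, p$w, bb$dx, ca$H, ca$W, ca$N)
    grads[[name]] <<- list(w = cb$dW, b = cb$db, gamma = bb$dgamma,
                           beta = bb$dbeta)
    cb$dx
  }

  pf <- model$params[["final"]]
  grads[["final"]] <- list(w = crossprod(fwd$final_in, dlogits),
                           b = colSums(dlogits))
  d <- dlogits %*% t(pf$w)

  # decoder (levels 1..D = reverse execution order)
  dskips <- vector("list", D)
  for (l in seq_len(D)) {
    d <- bwd_block(paste0("dec", l, "_2"), d)
    d <- bwd_block(paste0("dec", l, "_1"), d)
    up_c <- caches[[paste0("upc", l)]]
    ca <- caches[[paste0("dec", l, "_1")]]
    dup <- d[, seq_len(up_c), drop = FALSE]
    dskips[[l]] <- d[, up_c + seq_len(ncol(d) - up_c), drop = FALSE]
    d <- upsample_bwd(fm(dup, ca$H, ca$W, ca$N))$m
  }

  # bottleneck chain
  for (i in rev(seq_along(cfg$dilations))) {
    d <- bwd_block(paste0("bott", i), d)
  }

  # encoder (levels D..1); d arrives at the pool output of level l
  for (l in rev(seq_len(D))) {
    ca <- caches[[paste0("enc", l, "_2")]]
    dpool <- pool_bwd(caches[[paste0("pool", l)]],
                      fm(d, ca$H %/% 2L, ca$W %/% 2L, ca$N))$m
    d <- dpool + dskips[[l]]
    d <- bwd_block(paste0("enc", l, "_2"), d)
    d <- bwd_block(paste0("enc", l, "_1"), d)
  }
  list(loss = loss, grads = grads)
}

#' @noRd
#' One Adam update; state holds first/second moments and the step count.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (name in names(grads)) {
    for (field in names(grads[[name]])) {
      g <- grads[[name]][[field]]
      key <- paste0(name, ".", field)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      params[[name]][[field]] <- params[[name]][[field]] -
        lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

#' Predict segmentation masks
#'
#' Runs the U-net in evaluation mode (batch-norm running statistics) and
#' returns the argmax label per pixel: 0 background, 1 blood pool,
#' 2 myocardium.
#'
#' @param model a trained `unet_model`.
#' @param x array `[H, W]` or `[H, W, N]` of grayscale images.
#' @return integer label array of the same spatial shape.
#' @export
predict_unet <- function(model, x) {
  single <- length(dim(x)) == 2L || is.null(dim(x))
  if (is.null(dim(x))) cmr_stop("data_error", "x must be a 2D or 3D array")
  if (single) dim(x) <- c(dim(x), 1L)
  fwd <- unet_fwd(model, x, train = FALSE)
  lab <- max.col(fwd$probs, ties.method = "first") - 1L
  out <- array(as.integer(lab), c(fwd$H, fwd$W, fwd$N))
  if (single) out[, , 1L] else out
}

#' Class probabilities from the U-net
#'
#' @param model a `unet_model`.
#' @param x single image `[H, W]`.
#' @return array `[H, W, n_classes]`; channels sum to 1 per pixel.
#' @export
predict_unet_probs <- function(model, x) {
  dim(x) <- c(dim(x), 1L)
  fwd <- unet_fwd(model, x, train = FALSE)
  array(fwd$probs, c(fwd$H, fwd$W, model$config$n_classes))
}

#' Train the U-net segmenter
#'
#' Mini-batch Adam training on (image, mask) pairs with on-the-fly spatial
#' augmentation (see [augment]). Deterministic given `config$seed`. Returns
#' the trained model with a per-epoch mean loss trace.
#'
#' @param images array `[H, W, N]` of grayscale training images.
#' @param masks integer array `[H, W, N]` of 3-class labels (0/1/2).
#' @param config a [segmenter_config].
#' @param verbose print per-epoch loss.
#' @return a `unet_model` with an added `loss_trace` field.
#' @export
train_segmenter <- function(images, masks, config, verbose = FALSE) {
  if (!all(dim(images) == dim(masks)))
    cmr_stop("data_error", "image/mask dimensions differ")
  n <- dim(images)[3]
  if (n < 8L) cmr_stop("data_error", "need at least 8 training pairs")
  model <- build_unet(config)
  state <- list(t = 0L, m = list(), v = list())
  set.seed(config$seed + 1L)
  trace <- numeric(config$epochs)
  lr <- config$learning_rate
  aug <- config$augmentation
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- images[, , take, drop = FALSE]
      yb <- masks[, , take, drop = FALSE]
      if (!is.null(aug)) {
        for (k in seq_along(take)) {
          a <- augment(xb[, , k], yb[, , k], aug,
                       seed = sample.int(.Machine$integer.max, 1L))
          xb[, , k] <- a$image
          yb[, , k] <- a$mask
        }
      }
      fwd <- unet_fwd(model, xb, train = TRUE)
      model <- fwd$model   # batch-norm running stats updated
      bwd <- unet_bwd(model, fwd, yb + 1L)
      upd <- adam_step(model$params, bwd$grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      losses <- c(losses, bwd$loss)
    }
    trace[epoch] <- mean(losses)
    lr <- lr * (1 - config$lr_decay)
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f", epoch, config$epochs,
                      trace[epoch]))
  }
  model$loss_trace <- trace
  model
}
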