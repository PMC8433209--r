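## Compact contracting/expanding (U-Net style) segmentation network,
## implemented natively: 3x3 same-padding convolutions as im2col + BLAS
## GEMM, ReLU, 2x2 max pooling, nearest-neighbour upsampling, optional
## skip connections between matching levels, a single final 1x1
## convolution, sigmoid output, binary cross-entropy loss, Adam updates.
## Each contracting/expanding block holds two convolutional layers; the
## output block holds one. Everything is plain R arrays [H, W, C]; the
## GEMMs go to the linked BLAS, which is where the arithmetic lives.

#' Network architecture specification
#'
#' `depth` contracting blocks (each: two 3x3 conv + ReLU, then 2x2 max
#' pool), a two-convolution bottleneck, `depth` expanding blocks (each:
#' 2x upsampling, optional skip concatenation, two 3x3 conv + ReLU), and
#' one final 1x1 convolution with sigmoid output. Level l halves the
#' spatial size and doubles the filter count relative to level l-1,
#' starting from `base_filters`.
#'
#' @param depth number of contracting (= expanding) blocks, >= 1.
#' @param base_filters filters at the first level, >= 1.
#' @param input_size spatial side of the (square, single-channel) input;
#'   must be divisible by `2^depth`.
#' @param skip_connections logical; `FALSE` is the ablation variant.
#' @return list of class `net_spec`.
#' @export
net_spec <- function(depth = 2, base_filters = 8, input_size = 256,
                     skip_connections = TRUE) {
  stopifnot(depth >= 1, base_filters >= 1, input_size >= 2^depth,
            input_size %% (2^depth) == 0)
  structure(list(depth = depth, base_filters = base_filters,
                 input_size = input_size,
                 skip_connections = isTRUE(skip_connections)),
            class = "net_spec")
}

## weight matrices are (k^2 * C_in) x C_out; He-scaled init
.conv_init <- function(c_in, c_out, k, rng) {
  list(W = matrix(rng$rnorm(k * k * c_in * c_out) * sqrt(2 / (k * k * c_in)),
                  k * k * c_in, c_out),
       b = rep(0, c_out), k = k, c_in = c_in, c_out = c_out)
}

#' Build a trainable segmentation network
#'
#' Allocates and He-initialises all convolution weights for a
#' [net_spec()]; initialisation is a pure function of `seed`.
#'
#' @param spec [net_spec()].
#' @param seed integer seed for weight initialisation.
#' @return list of class `unet` with `spec`, `layers`, `n_params`.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "net_spec"))
  rng <- .seeded_rng(seed)
  f <- spec$base_filters * 2^(seq_len(spec$depth) - 1)
  layers <- list(enc = list(), dec = list())
  c_in <- 1
  for (i in seq_len(spec$depth)) {
    layers$enc[[i]] <- list(conv1 = .conv_init(c_in, f[i], 3, rng),
                            conv2 = .conv_init(f[i], f[i], 3, rng))
    c_in <- f[i]
  }
  fb <- f[spec$depth] * 2
  layers$bottleneck <- list(conv1 = .conv_init(c_in, fb, 3, rng),
                            conv2 = .conv_init(fb, fb, 3, rng))
  c_in <- fb
  for (i in rev(seq_len(spec$depth))) {
    c_cat <- if (spec$skip_connections) c_in + f[i] else c_in
    layers$dec[[i]] <- list(conv1 = .conv_init(c_cat, f[i], 3, rng),
                            conv2 = .conv_init(f[i], f[i], 3, rng))
    c_in <- f[i]
  }
  layers$head <- .conv_init(c_in, 1, 1, rng)
  n_params <- sum(vapply(rapply(layers, function(z) length(z), how = "unlist"),
                         identity, 0))
  structure(list(spec = spec, layers = layers, n_params = n_params),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("compact encoder-decoder: depth %d, base %d filters, %s skips, %d parameters\n",
              x$spec$depth, x$spec$base_filters,
              if (x$spec$skip_connections) "with" else "without", x$n_params))
  invisible(x)
}

## ---- array ops ----------------------------------------------------------

.im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    cols[, ((k - 1) * C + 1):(k * C)] <-
      matrix(xp[(1:H) + di, (1:W) + dj, , drop = FALSE], H * W, C)
  }
  cols
}

.col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    dxp[(1:H) + di, (1:W) + dj, ] <-
      dxp[(1:H) + di, (1:W) + dj, , drop = FALSE] +
      array(dcols[, ((k - 1) * C + 1):(k * C)], c(H, W, C))
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

.conv_fwd <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]
  if (p$k == 1) {
    xm <- matrix(x, H * W, p$c_in)
    out <- sweep(xm %*% p$W, 2, p$b, "+")
  } else {
    cols <- .im2col3(x)
    out <- sweep(cols %*% p$W, 2, p$b, "+")
  }
  list(out = array(out, c(H, W, p$c_out)), x = x)
}

.conv_bwd <- function(dout, cache, p) {
  d <- dim(cache$x); H <- d[1]; W <- d[2]
  dom <- matrix(dout, H * W, p$c_out)
  if (p$k == 1) {
    xm <- matrix(cache$x, H * W, p$c_in)
    dW <- crossprod(xm, dom)
    dx <- array(dom %*% t(p$W), c(H, W, p$c_in))
  } else {
    cols <- .im2col3(cache$x)      # recomputed: trades FLOPs for memory
    dW <- crossprod(cols, dom)
    dx <- .col2im3(dom %*% t(p$W), H, W, p$c_in)
  }
  list(dx = dx, dW = dW, db = colSums(dom))
}

.relu_fwd <- function(x) list(out = pmax(x, 0), x = x)
.relu_bwd <- function(dout, cache) dout * (cache$x > 0)

.pool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2)
  j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  ga <- a == out; gb <- (b == out) & !ga
  gc <- (cc == out) & !ga & !gb; gd <- !(ga | gb | gc)
  list(out = out, g = list(ga, gb, gc, gd), H = H, W = W, C = C)
}

.pool_bwd <- function(dout, cache) {
  H <- cache$H; W <- cache$W; C <- cache$C
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2)
  j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  dx <- array(0, c(H, W, C))
  dx[i1, j1, ] <- dout * cache$g[[1]]
  dx[i2, j1, ] <- dout * cache$g[[2]]
  dx[i1, j2, ] <- dout * cache$g[[3]]
  dx[i2, j2, ] <- dout * cache$g[[4]]
  dx
}

.up_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

.up_bwd <- function(dout) {
  d <- dim(dout); H <- d[1] / 2; W <- d[2] / 2
  i1 <- seq(1, d[1], 2); i2 <- seq(2, d[1], 2)
  j1 <- seq(1, d[2], 2); j2 <- seq(2, d[2], 2)
  dout[i1, j1, , drop = FALSE] + dout[i2, j1, , drop = FALSE] +
    dout[i1, j2, , drop = FALSE] + dout[i2, j2, , drop = FALSE]
}

## two conv+ReLU layers; returns output and the caches backward needs
.block_fwd <- function(x, blk) {
  c1 <- .conv_fwd(x, blk$conv1); r1 <- .relu_fwd(c1$out)
  c2 <- .conv_fwd(r1$out, blk$conv2); r2 <- .relu_fwd(c2$out)
  list(out = r2$out, c1 = c1, r1 = r1, c2 = c2, r2 = r2)
}

.block_bwd <- function(dout, cache, blk) {
  d2 <- .relu_bwd(dout, cache$r2)
  g2 <- .conv_bwd(d2, cache$c2, blk$conv2)
  d1 <- .relu_bwd(g2$dx, cache$r1)
  g1 <- .conv_bwd(d1, cache$c1, blk$conv1)
  list(dx = g1$dx,
       grads = list(conv1 = list(dW = g1$dW, db = g1$db),
                    conv2 = list(dW = g2$dW, db = g2$db)))
}

## full forward pass; x is [H, W, 1]
.net_fwd <- function(net, x) {
  sp <- net$spec; L <- net$layers
  caches <- list(enc = list(), pool = list(), dec = list())
  skips <- list()
  h <- x
  for (i in seq_len(sp$depth)) {
    e <- .block_fwd(h, L$enc[[i]])
    caches$enc[[i]] <- e
    skips[[i]] <- e$out
    p <- .pool_fwd(e$out)
    caches$pool[[i]] <- p
    h <- p$out
  }
  bo <- .block_fwd(h, L$bottleneck)
  caches$bottleneck <- bo
  h <- bo$out
  for (i in rev(seq_len(sp$depth))) {
    hu <- .up_fwd(h)
    if (sp$skip_connections) {
      d <- dim(hu)
      hu <- array(c(hu, skips[[i]]), c(d[1], d[2], d[3] + dim(skips[[i]])[3]))
    }
    dc <- .block_fwd(hu, L$dec[[i]])
    caches$dec[[i]] <- c(dc, list(c_up = dim(h)[3]))
    h <- dc$out
  }
  hd <- .conv_fwd(h, L$head)
  caches$head <- hd
  z <- hd$out[, , 1]
  list(z = z, p = stats::plogis(z), caches = caches)
}

## backward from dL/dz; returns gradients mirroring net$layers
.net_bwd <- function(net, fw, dz) {
  sp <- net$spec; L <- net$layers; caches <- fw$caches
  grads <- list(enc = vector("list", sp$depth),
                dec = vector("list", sp$depth))
  d <- dim(caches$head$x)
  gh <- .conv_bwd(array(dz, c(d[1], d[2], 1)), caches$head, L$head)
  grads$head <- list(dW = gh$dW, db = gh$db)
  dh <- gh$dx
  dskip <- vector("list", sp$depth)
  for (i in seq_len(sp$depth)) {           # decoder, shallow -> deep
    bb <- .block_bwd(dh, caches$dec[[i]], L$dec[[i]])
    grads$dec[[i]] <- bb$grads
    dhu <- bb$dx
    c_up <- caches$dec[[i]]$c_up
    if (sp$skip_connections) {
      dskip[[i]] <- dhu[, , (c_up + 1):dim(dhu)[3], drop = FALSE]
      dhu <- dhu[, , seq_len(c_up), drop = FALSE]
    }
    dh <- .up_bwd(dhu)
  }
  bb <- .block_bwd(dh, caches$bottleneck, L$bottleneck)
  grads$bottleneck <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(sp$depth))) {      # encoder, deep -> shallow
    de <- .pool_bwd(dh, caches$pool[[i]])
    if (sp$skip_connections) de <- de + dskip[[i]]
    bb <- .block_bwd(de, caches$enc[[i]], L$enc[[i]])
    grads$enc[[i]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

## per-frame standardisation to zero mean / unit variance
.standardize_frame <- function(frame) {
  s <- stats::sd(frame)
  z <- (frame - mean(frame)) / if (s > 0) s else 1
  array(z, c(dim(frame), 1))
}

.bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## ---- training -----------------------------------------------------------

## walk net$layers and grads in lockstep, applying Adam per tensor
.adam_step <- function(net, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  upd_conv <- function(p, g, mC, vC) {
    for (nm in c("W", "b")) {
      gn <- if (nm == "W") g$dW else g$db
      mC[[nm]] <- beta1 * mC[[nm]] + (1 - beta1) * gn
      vC[[nm]] <- beta2 * vC[[nm]] + (1 - beta2) * gn^2
      mhat <- mC[[nm]] / (1 - beta1^t)
      vhat <- vC[[nm]] / (1 - beta2^t)
      p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(p = p, m = mC, v = vC)
  }
  for (i in seq_len(net$spec$depth)) {
    for (cv in c("conv1", "conv2")) {
      r <- upd_conv(net$layers$enc[[i]][[cv]], grads$enc[[i]][[cv]],
                    state$m$enc[[i]][[cv]], state$v$enc[[i]][[cv]])
      net$layers$enc[[i]][[cv]] <- r$p
      state$m$enc[[i]][[cv]] <- r$m; state$v$enc[[i]][[cv]] <- r$v
      r <- upd_conv(net$layers$dec[[i]][[cv]], grads$dec[[i]][[cv]],
                    state$m$dec[[i]][[cv]], state$v$dec[[i]][[cv]])
      net$layers$dec[[i]][[cv]] <- r$p
      state$m$dec[[i]][[cv]] <- r$m; state$v$dec[[i]][[cv]] <- r$v
    }
  }
  for (cv in c("conv1", "conv2")) {
    r <- upd_conv(net$layers$bottleneck[[cv]], grads$bottleneck[[cv]],
                  state$m$bottleneck[[cv]], state$v$bottleneck[[cv]])
    net$layers$bottleneck[[cv]] <- r$p
    state$m$bottleneck[[cv]] <- r$m; state$v$bottleneck[[cv]] <- r$v
  }
  r <- upd_conv(net$layers$head, grads$head, state$m$head, state$v$head)
  net$layers$head <- r$p; state$m$head <- r$m; state$v$head <- r$v
  list(net = net, state = state)
}

## Adam moment tensors shaped like the weights, initialised to zero
.zero_like_layers <- function(layers) {
  zero_conv <- function(p) list(W = p$W * 0, b = p$b * 0)
  z <- list(enc = lapply(layers$enc, function(b)
    list(conv1 = zero_conv(b$conv1), conv2 = zero_conv(b$conv2))),
    dec = lapply(layers$dec, function(b)
      list(conv1 = zero_conv(b$conv1), conv2 = zero_conv(b$conv2))),
    bottleneck = list(conv1 = zero_conv(layers$bottleneck$conv1),
                      conv2 = zero_conv(layers$bottleneck$conv2)),
    head = zero_conv(layers$head))
  z
}

#' Train the segmentation network
#'
#' Per-image Adam updates on binary cross-entropy against the {0, 255}
#' cytoplasm masks, with per-frame input standardisation. Logs per-epoch
#' train/validation loss and pixel accuracy and returns the checkpoint
#' with the best validation accuracy. The run is a pure function of
#' (network, data, `seed`): the shuffle order is the only randomness.
#'
#' @param net [build_network()] output.
#' @param train_set,val_set lists of `list(frame, mask)` pairs (0--255
#'   frames, {0, 255} masks), e.g. from [make_benchmark()].
#' @param epochs training epochs.
#' @param seed integer seed for the per-epoch shuffle.
#' @param lr Adam learning rate.
#' @return list of class `trained_unet`: `net` (best-validation
#'   checkpoint), `history` (data.frame `epoch, train_loss, train_acc,
#'   val_loss, val_acc`), `best_epoch`.
#' @export
train_network <- function(net, train_set, val_set, epochs = 10, seed = 1,
                          lr = 1e-3) {
  if (length(train_set) == 0) stop("empty training set")
  if (length(val_set) == 0) stop("empty validation set")
  rng <- .seeded_rng(seed)
  state <- list(m = .zero_like_layers(net$layers),
                v = .zero_like_layers(net$layers))
  t_adam <- 0
  hist <- data.frame()
  best <- list(acc = -Inf, net = net, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- rng$sample_int(length(train_set))
    tl <- 0; ta <- 0
    for (ix in ord) {
      x <- .standardize_frame(train_set[[ix]]$frame)
      y <- (train_set[[ix]]$mask > 0) * 1
      fw <- .net_fwd(net, x)
      tl <- tl + .bce_loss(fw$p, y)
      ta <- ta + mean((fw$p > 0.5) == (y > 0.5))
      dz <- (fw$p - y) / length(y)
      grads <- .net_bwd(net, fw, dz)
      t_adam <- t_adam + 1
      st <- .adam_step(net, grads, state, lr, t_adam)
      net <- st$net; state <- st$state
    }
    ev <- evaluate_network(net, val_set)
    hist <- rbind(hist, data.frame(
      epoch = ep, train_loss = tl / length(train_set),
      train_acc = ta / length(train_set),
      val_loss = ev$loss, val_acc = ev$pixel_accuracy))
    if (ev$pixel_accuracy > best$acc)
      best <- list(acc = ev$pixel_accuracy, net = net, epoch = ep)
  }
  structure(list(net = best$net, history = hist, best_epoch = best$epoch),
            class = "trained_unet")
}

#' Evaluate a network on an image/mask set
#'
#' @param net `unet` or `trained_unet`.
#' @param dataset list of `list(frame, mask)` pairs.
#' @return list `loss` (mean BCE), `pixel_accuracy`, `dice` (means over
#'   the set).
#' @export
evaluate_network <- function(net, dataset) {
  if (inherits(net, "trained_unet")) net <- net$net
  loss <- acc <- dic <- 0
  for (d in dataset) {
    fw <- .net_fwd(net, .standardize_frame(d$frame))
    y <- (d$mask > 0) * 1
    loss <- loss + .bce_loss(fw$p, y)
    m <- segmentation_metrics((fw$p > 0.5) * 255, d$mask)
    acc <- acc + m$pixel_accuracy; dic <- dic + m$dice
  }
  n <- length(dataset)
  list(loss = loss / n, pixel_accuracy = acc / n, dice = dic / n)
}

#' Predict a {0, 255} cytoplasm mask for one frame
#'
#' Forward pass, probability threshold 0.5, then largest-component
#' cleanup so the mask satisfies the single-object convention.
#'
#' @param net `unet` or `trained_unet`.
#' @param frame numeric matrix, 0--255.
#' @param min_area minimum component area, px.
#' @return matrix in {0, 255}.
#' @export
predict_mask <- function(net, frame, min_area = 50) {
  if (inherits(net, "trained_unet")) net <- net$net
  fw <- .net_fwd(net, .standardize_frame(frame))
  bin <- fw$p > 0.5
  keep <- .largest_component(bin, min_area)
  matrix(255 * as.numeric(keep), nrow(frame), ncol(frame))
}
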