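test_that("network output shape equals input shape at full frame size", {
  net <- build_network(net_spec(depth = 4, base_filters = 16,
                                input_size = 256), seed = 1)
  x <- array(stats::rnorm(256 * 256), c(256, 256, 1))
  fw <- cryoperm:::.net_fwd(net, x)
  expect_equal(dim(fw$p), c(256, 256))
  expect_true(all(fw$p > 0 & fw$p < 1))
  expect_gt(net$n_params, 0)
})

test_that("minimal legal network constructs and runs", {
  net <- build_network(net_spec(depth = 1, base_filters = 1,
                                input_size = 16), seed = 1)
  fw <- cryoperm:::.net_fwd(net, array(stats::rnorm(256), c(16, 16, 1)))
  expect_equal(dim(fw$p), c(16, 16))
  expect_error(net_spec(depth = 3, base_filters = 4, input_size = 20))
  expect_error(net_spec(depth = 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(7)
  net <- build_network(net_spec(depth = 2, base_filters = 2,
                                input_size = 8), seed = 3)
  x <- array(stats::rnorm(64), c(8, 8, 1))
  y <- matrix(stats::rbinom(64, 1, 0.5), 8, 8)
  fw <- cryoperm:::.net_fwd(net, x)
  gr <- cryoperm:::.net_bwd(net, fw, (fw$p - y) / length(y))
  loss_at <- function(n) cryoperm:::.bce_loss(cryoperm:::.net_fwd(n, x)$p, y)
  fd_check <- function(get, set, g) {
    idx <- round(seq(1, length(g), length.out = 4))
    for (i in idx) {
      eps <- 1e-5
      np <- net; w <- get(np); w[i] <- w[i] + eps; np <- set(np, w)
      f1 <- loss_at(np)
      nm <- net; w <- get(nm); w[i] <- w[i] - eps; nm <- set(nm, w)
      f0 <- loss_at(nm)
      num <- (f1 - f0) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-8), 1e-4)
    }
  }
  fd_check(function(n) n$layers$enc[[1]]$conv1$W,
           function(n, w) { n$layers$enc[[1]]$conv1$W <- w; n },
           gr$enc[[1]]$conv1$dW)
  fd_check(function(n) n$layers$dec[[2]]$conv2$W,
           function(n, w) { n$layers$dec[[2]]$conv2$W <- w; n },
           gr$dec[[2]]$conv2$dW)
  fd_check(function(n) n$layers$head$W,
           function(n, w) { n$layers$head$W <- w; n },
           gr$head$dW)
})

test_that("the network can overfit a single frame", {
  bm <- bench64()
  net <- build_network(net_spec(depth = 2, base_filters = 8,
                                input_size = 64), seed = 1)
  tr <- train_network(net, bm$train[1], bm$train[1], epochs = 150,
                      seed = 2, lr = 3e-3)
  expect_lt(utils::tail(tr$history$train_loss, 1), 0.01)
})

test_that("scaled benchmark training reaches high validation accuracy", {
  tr <- trained_net64()
  expect_gte(max(tr$history$val_acc), 0.97)
  expect_equal(nrow(tr$history), 10)
  ## loss decreases overall
  expect_lt(utils::tail(tr$history$train_loss, 1), tr$history$train_loss[1])
})

test_that("training is deterministic given the seed", {
  bm <- bench64()
  run <- function() {
    net <- build_network(net_spec(depth = 2, base_filters = 8,
                                  input_size = 64), seed = 1)
    train_network(net, bm$train[1:20], bm$val[1:5], epochs = 2,
                  seed = 2, lr = 2e-3)$history
  }
  expect_identical(run(), run())
})

test_that("removing skip connections lowers validation accuracy", {
  bm <- bench64()
  with_skip <- trained_net64()
  net0 <- build_network(net_spec(depth = 2, base_filters = 8,
                                 input_size = 64,
                                 skip_connections = FALSE), seed = 1)
  no_skip <- train_network(net0, bm$train, bm$val, epochs = 10,
                           seed = 2, lr = 2e-3)
  expect_lt(max(no_skip$history$val_acc), max(with_skip$history$val_acc))
})

test_that("trained network agrees with the classical backend on clean frames", {
  tr <- trained_net64()
  spec <- render_spec(image_size = 64, noise_sigma = 0,
                      illumination_gradient = 0, r0 = 18,
                      zona_thickness = 5)
  fm <- render_frame(spec, 18)
  m_net <- predict_mask(tr, fm$frame)
  m_cls <- segment_classical(fm$frame, min_area = 50)
  expect_gte(segmentation_metrics(m_net, m_cls)$dice, 0.97)
})

test_that("degenerate training inputs error", {
  net <- build_network(net_spec(depth = 1, base_filters = 2,
                                input_size = 16), seed = 1)
  expect_error(train_network(net, list(), list(), epochs = 1), "empty")
})
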