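test_that("layer-shape arithmetic matches the hand trace", {
  nc <- net_config()
  expect_equal(c(nc$h1, nc$w1), c(7, 104))
  expect_equal(c(nc$h2, nc$w2), c(3, 52))
  expect_equal(nc$flat, 3 * 52 * 50)  # 7800
  expect_error(net_config(input_hw = c(1, 20)),
               "first max-pooling")
  expect_error(net_config(input_hw = c(2, 20)),
               "second max-pooling")
  expect_error(net_config(conv1_kernel = 4), "odd")
  expect_error(net_config(dropout_rate = 1), "dropout_rate")
})

test_that("model building is deterministic and supports grayscale input", {
  m1 <- build_model(net_config(), seed = 42)
  m2 <- build_model(net_config(), seed = 42)
  expect_identical(m1$weights, m2$weights)
  m3 <- build_model(net_config(), seed = 43)
  expect_false(identical(m1$weights, m3$weights))
  g <- build_model(net_config(in_channels = 1), seed = 1)
  expect_equal(ncol(g$weights$W1), 25)  # 5*5*1
})

test_that("the learning-rate schedule follows inverse decay", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.01)
  expect_equal(lr_at(10, cfg), 0.01 * 10^(-0.75), tolerance = 1e-12)
  lrs <- lr_at(0:200, cfg)
  expect_true(all(diff(lrs) < 0))  # strictly decreasing
  expect_error(lr_at(-1, cfg), ">= 0")
})

test_that("the Euclidean loss uses the 1/(2N) normalization", {
  expect_equal(euclidean_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(euclidean_loss(1, 0), 0.5)
  expect_equal(euclidean_loss(c(1, 1), c(0, 0)), 0.5)
  expect_error(euclidean_loss(numeric(0), numeric(0)), "empty")
  expect_error(euclidean_loss(1:3, 1:2), "equal length")
})

test_that("the compiled forward pass matches an independent R implementation", {
  nc <- net_config(input_hw = c(8, 12), in_channels = 2, conv1_maps = 3,
                   conv2_maps = 4, fc_hidden = 5, dropout_rate = 0)
  set.seed(2)
  X <- matrix(runif(8 * 12 * 2 * 6), 8 * 12 * 2, 6)
  w <- rgbvi:::init_weights(nc, 3)
  got <- rgbvi:::cnn_predict_core(X, w, unclass(nc))
  ref <- ref_forward(X, w, nc)
  expect_equal(as.numeric(got), ref, tolerance = 1e-5)
})

test_that("analytic gradients match numerical derivatives of the R oracle", {
  nc <- net_config(input_hw = c(8, 12), in_channels = 2, conv1_maps = 3,
                   conv2_maps = 4, fc_hidden = 5, dropout_rate = 0)
  set.seed(2)
  X <- matrix(runif(8 * 12 * 2 * 6), 8 * 12 * 2, 6)
  y <- runif(6)
  w <- rgbvi:::init_weights(nc, 3)
  an <- rgbvi:::cnn_loss_grad_core(X, y, w, unclass(nc))
  expect_equal(an$loss, euclidean_loss(ref_forward(X, w, nc), y),
               tolerance = 1e-6)
  lossR <- function(wmod) euclidean_loss(ref_forward(X, wmod, nc), y)
  set.seed(4)
  for (par in names(w)) {
    idx <- sample(length(w[[par]]), min(4, length(w[[par]])))
    ng <- vapply(idx, function(i) {
      eps <- 1e-6
      wp <- w; wp[[par]][i] <- wp[[par]][i] + eps
      wm <- w; wm[[par]][i] <- wm[[par]][i] - eps
      (lossR(wp) - lossR(wm)) / (2 * eps)
    }, numeric(1))
    ag <- an$grads[[par]][idx]
    expect_equal(ag, ng, tolerance = 1e-3, info = par)
  }
})

test_that("training is reproducible and reduces the loss", {
  nc <- tiny_net()
  s <- linear_rule_samples(80, nc, seed = 31)
  tc <- train_config(batch_size = 16, epochs = 8, seed = 7)
  f1 <- vi_dnn(s, net = nc, train = tc)
  f2 <- vi_dnn(s, net = nc, train = tc)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$loss, f2$loss)
  f3 <- vi_dnn(s, net = nc, train = train_config(batch_size = 16, epochs = 8,
                                                 seed = 8))
  expect_false(identical(f1$weights, f3$weights))
  # descent contract: running loss goes down
  expect_lt(mean(tail(f1$loss, 5)), mean(head(f1$loss, 5)))
  # the logged schedule matches lr_at
  expect_equal(f1$lr, lr_at(seq_along(f1$lr) - 1, tc), tolerance = 1e-12)
})

test_that("prediction is deterministic with dropout inert", {
  nc <- tiny_net()
  s <- linear_rule_samples(40, nc, seed = 32)
  fit <- vi_dnn(s, net = nc, train = train_config(batch_size = 8, epochs = 4,
                                                  seed = 1))
  p <- replicate(5, predict(fit, s))
  expect_equal(apply(p, 1, var), rep(0, 40))  # zero variance across calls
  img <- sample_image(s, 3)
  expect_length(predict(fit, img), 1)
  expect_error(predict(fit, array(0, c(5, 5, 3))), "12 x 32 x 3")
})

test_that("a singleton training set is memorized to high precision", {
  nc <- net_config(input_hw = c(8, 16), in_channels = 3, conv1_maps = 4,
                   conv2_maps = 4, fc_hidden = 8, dropout_rate = 0)
  set.seed(33)
  img <- matrix(runif(8 * 16 * 3, 0, 0.3), ncol = 1)
  s <- as_plot_samples(img[, rep(1, 16), drop = FALSE], c(8L, 16L, 3L),
                       rep(0.7, 16))
  fit <- vi_dnn(s, net = nc,
                train = train_config(batch_size = 16, epochs = 400, seed = 2,
                                     augment_flip = FALSE))
  expect_lt(abs(predict(fit, s)[1] - 0.7), 1e-3)
})

test_that("a linear generative rule is recovered on held-out data", {
  nc <- tiny_net()
  train_set <- linear_rule_samples(200, nc, seed = 34)
  test_set <- linear_rule_samples(60, nc, seed = 35)
  fit <- vi_dnn(train_set, net = nc,
                train = train_config(batch_size = 36, epochs = 60, seed = 3))
  rmse <- sqrt(mean((predict(fit, test_set) - test_set$meta$target_vi)^2))
  expect_lt(rmse, 0.02)
})

test_that("flip augmentation leaves targets untouched and flips only the long axis", {
  nc <- tiny_net()
  s <- linear_rule_samples(30, nc, seed = 36)
  fit <- vi_dnn(s, net = nc, train = train_config(batch_size = 10, epochs = 3,
                                                  seed = 4, augment_flip = TRUE))
  expect_identical(fit$targets, s$meta$target_vi)
  # a horizontally symmetric image predicts identically to its flip
  img <- sample_image(s, 1)
  sym <- (img + img[, ncol(img):1, , drop = FALSE]) / 2
  expect_equal(predict(fit, sym),
               predict(fit, sym[, ncol(sym):1, , drop = FALSE]),
               tolerance = 1e-6)
})

test_that("invalid inputs fail with informative errors", {
  nc <- tiny_net()
  s <- linear_rule_samples(10, nc, seed = 37)
  s$meta$target_vi[3] <- NA
  expect_error(vi_dnn(s, net = nc), "finite")
  s2 <- linear_rule_samples(10, nc, seed = 37)
  expect_error(vi_dnn(s2, net = net_config()), "expects")
})

test_that("models survive a save/load round trip", {
  nc <- tiny_net()
  s <- linear_rule_samples(20, nc, seed = 38)
  fit <- vi_dnn(s, net = nc, train = train_config(batch_size = 10, epochs = 2,
                                                  seed = 5))
  dir <- file.path(tempdir(), "vi-dnn-model")
  save_vi_dnn(fit, dir)
  back <- load_vi_dnn(dir)
  expect_equal(predict(back, s), predict(fit, s))
  unlink(dir, recursive = TRUE)
})
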