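#' Architecture of the convolutional vegetation-index regressor
#'
#' The network maps an RGB (or grayscale) plot image to a scalar vegetation
#' index through `conv(20, 5x5) -> maxpool(2x2) -> conv(50, 5x5) ->
#' maxpool(2x2) -> flatten -> fc(500) -> ReLU -> dropout -> fc(1)`. Both
#' convolutions are same-padded: with valid convolutions the 15-pixel plot
#' height would collapse to zero before the second pooling layer, so the
#' stack is only realizable with padding. Pooling uses non-overlapping 2x2
#' windows with floor division, so `(15, 208)` shrinks to `(7, 104)` and then
#' `(3, 52)`.
#'
#' @param input_hw Image height and width, default `c(15, 208)`.
#' @param in_channels 3 for RGB, 1 for grayscale.
#' @param conv1_maps,conv2_maps Feature maps of the two convolution layers.
#' @param conv1_kernel,conv2_kernel Odd square-kernel sizes.
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param dropout_rate Dropout probability in `[0, 1)`, active only during
#'   training.
#' @return An object of class `net_config` with derived layer shapes.
#' @export
#' @examples
#' net_config()$flat  # 3 * 52 * 50 = 7800
net_config <- function(input_hw = c(15, 208), in_channels = 3,
                       conv1_maps = 20, conv1_kernel = 5,
                       conv2_maps = 50, conv2_kernel = 5,
                       fc_hidden = 500, dropout_rate = 0.5) {
  if (length(input_hw) != 2 || any(input_hw < 1))
    stop("`input_hw` must be (height, width), both >= 1", call. = FALSE)
  if (conv1_kernel %% 2 == 0 || conv2_kernel %% 2 == 0)
    stop("kernel sizes must be odd for same-padding", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  h <- as.integer(input_hw[1]); w <- as.integer(input_hw[2])
  h1 <- h %/% 2L; w1 <- w %/% 2L
  if (h1 < 1 || w1 < 1)
    stop(sprintf("input %d x %d collapses to zero at the first max-pooling layer",
                 h, w), call. = FALSE)
  h2 <- h1 %/% 2L; w2 <- w1 %/% 2L
  if (h2 < 1 || w2 < 1)
    stop(sprintf("pooled size %d x %d collapses to zero at the second max-pooling layer",
                 h1, w1), call. = FALSE)
  structure(list(
    h = h, w = w, c = as.integer(in_channels),
    conv1_maps = as.integer(conv1_maps), conv1_kernel = as.integer(conv1_kernel),
    conv2_maps = as.integer(conv2_maps), conv2_kernel = as.integer(conv2_kernel),
    fc_hidden = as.integer(fc_hidden), dropout_rate = dropout_rate,
    h1 = h1, w1 = w1, h2 = h2, w2 = w2,
    flat = h2 * w2 * as.integer(conv2_maps)
  ), class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat("Convolutional VI regressor\n")
  cat(sprintf("  input %d x %d x %d\n", x$h, x$w, x$c))
  cat(sprintf("  conv %d @ %dx%d (same) -> pool 2x2 -> %d x %d\n",
              x$conv1_maps, x$conv1_kernel, x$conv1_kernel, x$h1, x$w1))
  cat(sprintf("  conv %d @ %dx%d (same) -> pool 2x2 -> %d x %d\n",
              x$conv2_maps, x$conv2_kernel, x$conv2_kernel, x$h2, x$w2))
  cat(sprintf("  flatten %d -> fc %d -> ReLU -> dropout %.2f -> fc 1\n",
              x$flat, x$fc_hidden, x$dropout_rate))
  invisible(x)
}

#' Optimizer settings for stochastic gradient descent
#'
#' Mirrors the classical SGD recipe: momentum, L2 weight decay, a mini-batch
#' of 72 randomly ordered images per iteration, random horizontal flip
#' augmentation, and an inverse-decay learning-rate policy
#' `lr(iter) = base_lr * (1 + lr_gamma * iter)^(-lr_power)` evaluated per
#' iteration (see [lr_at()]).
#'
#' @param base_lr Initial learning rate (0.01).
#' @param momentum SGD momentum in `[0, 1)` (0.9).
#' @param weight_decay L2 penalty coefficient (5e-4).
#' @param lr_power Decay exponent (0.75).
#' @param lr_gamma Decay coefficient of the schedule (0.9).
#' @param batch_size Mini-batch size (72).
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed for initialization, shuffling, flips and dropout.
#' @param augment_flip Randomly flip images along their long axis with
#'   probability 1/2 (targets unchanged; row plots are left-right symmetric).
#' @return An object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.01, momentum = 0.9, weight_decay = 5e-4,
                         lr_power = 0.75, lr_gamma = 0.9, batch_size = 72,
                         epochs = 50, seed = 1L, augment_flip = TRUE) {
  stopifnot_number(base_lr, "base_lr", 1e-12)
  stopifnot_number(momentum, "momentum", 0, 1 - 1e-12)
  stopifnot_number(weight_decay, "weight_decay", 0)
  stopifnot_number(batch_size, "batch_size", 1)
  stopifnot_number(epochs, "epochs", 1)
  structure(list(base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay, lr_power = lr_power,
                 lr_gamma = lr_gamma, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment_flip = isTRUE(augment_flip)),
            class = "train_config")
}

#' Inverse-decay learning-rate schedule
#'
#' `lr(iter) = base_lr * (1 + lr_gamma * iter)^(-lr_power)`, with iterations
#' counted from zero, so `lr_at(0, cfg)` equals the base learning rate.
#'
#' @param iter Iteration number(s), `>= 0`.
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
#' @examples
#' lr_at(0, train_config())   # 0.01
#' lr_at(10, train_config())  # 0.01 * 10^-0.75
lr_at <- function(iter, cfg = train_config()) {
  if (any(iter < 0)) stop("`iter` must be >= 0", call. = FALSE)
  cfg$base_lr * (1 + cfg$lr_gamma * iter)^(-cfg$lr_power)
}

#' Euclidean regression loss
#'
#' `(1 / 2N) * sum((pred - target)^2)`, the real-valued Euclidean loss with
#' the 1/(2N) normalization convention of classical deep-learning frameworks.
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @return A single number.
#' @export
#' @examples
#' euclidean_loss(1, 0)       # 0.5
#' euclidean_loss(c(1, 1), c(0, 0))  # 0.5
euclidean_loss <- function(predictions, targets) {
  if (length(predictions) == 0L) stop("empty batch", call. = FALSE)
  if (length(predictions) != length(targets))
    stop("`predictions` and `targets` must have equal length", call. = FALSE)
  sum((predictions - targets)^2) / (2 * length(predictions))
}

# Deterministic initialization: conv kernels are small-variance Gaussians
# with sd 1/sqrt(fan-in); fc layers are scaled-uniform (Glorot); biases zero.
init_weights <- function(net, seed) {
  with_seed(seed, {
    fan1 <- net$conv1_kernel^2 * net$c
    fan2 <- net$conv2_kernel^2 * net$conv1_maps
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
    list(
      W1 = matrix(rnorm(net$conv1_maps * fan1, 0, 1 / sqrt(fan1)),
                  net$conv1_maps, fan1),
      b1 = numeric(net$conv1_maps),
      W2 = matrix(rnorm(net$conv2_maps * fan2, 0, 1 / sqrt(fan2)),
                  net$conv2_maps, fan2),
      b2 = numeric(net$conv2_maps),
      W3 = glorot(net$fc_hidden, net$flat),
      b3 = numeric(net$fc_hidden),
      W4 = glorot(1L, net$fc_hidden),
      b4 = numeric(1L)
    )
  })
}

#' Build an untrained convolutional VI regressor
#'
#' Deterministic weight initialization for a given seed; two builds with the
#' same seed produce identical weights.
#'
#' @param net A [net_config()].
#' @param seed Integer seed.
#' @return A `vi_dnn` object with zero training iterations.
#' @export
build_model <- function(net = net_config(), seed = 1L) {
  structure(list(net = net, train = NULL,
                 weights = init_weights(net, substream_seed(seed, "init")),
                 loss = numeric(0), lr = numeric(0), fitted = NULL,
                 targets = NULL, meta = NULL, call = match.call()),
            class = "vi_dnn")
}

samples_matrix <- function(x, net) {
  if (inherits(x, "plot_samples")) {
    if (!identical(as.integer(x$dim), c(net$h, net$w, net$c)))
      stop(sprintf("samples are %s but the network expects %d x %d x %d",
                   paste(x$dim, collapse = " x "), net$h, net$w, net$c),
           call. = FALSE)
    return(x$x)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!identical(as.integer(dim(x)), c(net$h, net$w, net$c)))
      stop(sprintf("image is %s but the network expects %d x %d x %d",
                   paste(dim(x), collapse = " x "), net$h, net$w, net$c),
           call. = FALSE)
    return(matrix(as.vector(x), ncol = 1L))
  }
  if (is.matrix(x)) {
    if (nrow(x) != net$h * net$w * net$c)
      stop(sprintf("matrix has %d rows but the network expects %d (h*w*c)",
                   nrow(x), net$h * net$w * net$c), call. = FALSE)
    return(x)
  }
  stop("`x` must be a plot_samples object, an H x W x C array, or a matrix of vectorized images",
       call. = FALSE)
}

#' Fit the convolutional vegetation-index regressor
#'
#' Trains the network of [net_config()] on plot samples by stochastic
#' gradient descent with momentum, L2 weight decay, the inverse-decay
#' learning-rate schedule of [lr_at()], random horizontal flips, and the
#' Euclidean loss of [euclidean_loss()]. Training is fully reproducible for a
#' given `train$seed`.
#'
#' @param samples A `plot_samples` object (see [sample_plots()]); targets are
#'   taken from `samples$meta$target_vi` unless `targets` is given.
#' @param net A [net_config()]; its `in_channels` must match the samples.
#' @param train A [train_config()].
#' @param targets Optional numeric response overriding the samples' targets.
#' @param init Optional initial weights (a `vi_dnn` or its weight list);
#'   defaults to fresh initialization from the training seed.
#' @return An object of class `vi_dnn` with components `weights`, `loss` and
#'   `lr` (per-iteration logs), `fitted`, `targets`, `net`, `train`. Methods:
#'   [predict.vi_dnn()], `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `plot`.
#' @export
vi_dnn <- function(samples, net = net_config(), train = train_config(),
                   targets = NULL, init = NULL) {
  x <- samples_matrix(samples, net)
  if (is.null(targets)) {
    if (!inherits(samples, "plot_samples"))
      stop("`targets` must be supplied when `samples` is not a plot_samples object",
           call. = FALSE)
    targets <- samples$meta$target_vi
  }
  if (ncol(x) < 1L) stop("training requires at least one sample", call. = FALSE)
  if (length(targets) != ncol(x))
    stop("number of targets must match number of samples", call. = FALSE)
  if (any(!is.finite(targets))) stop("targets must be finite", call. = FALSE)
  if (is.null(init)) {
    w0 <- init_weights(net, substream_seed(train$seed, "init"))
    # start the output neuron at the mean response so the global offset --
    # the component the decaying schedule moves slowest -- needs no learning
    w0$b4 <- mean(targets)
  } else {
    w0 <- if (inherits(init, "vi_dnn")) init$weights else init
  }
  fit <- cnn_train_core(x, as.numeric(targets), w0, unclass(net),
                        unclass(train), substream_seed(train$seed, "sgd"))
  fitted <- as.numeric(cnn_predict_core(x, fit$weights, unclass(net)))
  structure(list(net = net, train = train, weights = fit$weights,
                 loss = as.numeric(fit$loss), lr = as.numeric(fit$lr),
                 fitted = fitted, targets = as.numeric(targets),
                 meta = if (inherits(samples, "plot_samples")) samples$meta else NULL,
                 call = match.call()),
            class = "vi_dnn")
}

#' Predict vegetation indices from RGB plot images
#'
#' Deterministic forward pass with dropout disabled; repeated calls on the
#' same image return identical values.
#'
#' @param object A fitted [vi_dnn()].
#' @param newdata A `plot_samples` object, a single `H x W x C` array, or a
#'   matrix of vectorized images (one per column).
#' @param ... Unused.
#' @return A numeric vector with one VI estimate per image.
#' @export
predict.vi_dnn <- function(object, newdata, ...) {
  x <- samples_matrix(newdata, object$net)
  as.numeric(cnn_predict_core(x, object$weights, unclass(object$net)))
}

#' @export
print.vi_dnn <- function(x, ...) {
  np <- sum(vapply(x$weights, length, 0L))
  cat(sprintf("Convolutional VI regressor: input %d x %d x %d, %d parameters\n",
              x$net$h, x$net$w, x$net$c, np))
  if (length(x$loss)) {
    cat(sprintf("  trained %d iterations; Euclidean loss %.3g -> %.3g\n",
                length(x$loss), x$loss[1], mean(tail_n(x$loss, 10))))
  } else cat("  untrained\n")
  invisible(x)
}

tail_n <- function(v, n) v[max(1L, length(v) - n + 1L):length(v)]

#' @export
summary.vi_dnn <- function(object, ...) {
  out <- list(net = object$net, n_params = sum(vapply(object$weights, length, 0L)),
              iterations = length(object$loss),
              loss_first = if (length(object$loss)) object$loss[1] else NA_real_,
              loss_last = if (length(object$loss)) mean(tail_n(object$loss, 10)) else NA_real_,
              train_rmse = if (!is.null(object$fitted))
                sqrt(mean((object$fitted - object$targets)^2)) else NA_real_)
  class(out) <- "summary.vi_dnn"
  out
}

#' @export
print.summary.vi_dnn <- function(x, ...) {
  print(x$net)
  cat(sprintf("  %d parameters; %d SGD iterations\n", x$n_params, x$iterations))
  cat(sprintf("  Euclidean loss: %.4g (first) -> %.4g (last-10 mean)\n",
              x$loss_first, x$loss_last))
  cat(sprintf("  training RMSE: %.4g\n", x$train_rmse))
  invisible(x)
}

#' @export
coef.vi_dnn <- function(object, ...) object$weights

#' @export
fitted.vi_dnn <- function(object, ...) object$fitted

#' @export
residuals.vi_dnn <- function(object, ...) object$targets - object$fitted

#' Training-loss trajectory of a fitted VI regressor
#'
#' @param x A fitted `vi_dnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vi_dnn <- function(x, ...) {
  if (!length(x$loss)) stop("model has not been trained", call. = FALSE)
  plot(seq_along(x$loss), x$loss, type = "l", log = "y",
       xlab = "SGD iteration", ylab = "Euclidean loss", ...)
  invisible(x)
}

#' Serialize a trained model to a directory
#'
#' Writes the architecture and optimizer settings as YAML and the weights as
#' an RDS archive with a format version.
#'
#' @param object A `vi_dnn`.
#' @param path Output directory (created if needed).
#' @export
save_vi_dnn <- function(object, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(format = 1L, net = unclass(object$net),
              train = if (!is.null(object$train)) unclass(object$train))
  writeLines(yaml::as.yaml(cfg), file.path(path, "model.yaml"))
  saveRDS(object$weights, file.path(path, "weights.rds"))
  invisible(path)
}

#' @rdname save_vi_dnn
#' @export
load_vi_dnn <- function(path) {
  cfg <- yaml::read_yaml(file.path(path, "model.yaml"))
  net <- do.call(net_config, list(
    input_hw = c(cfg$net$h, cfg$net$w), in_channels = cfg$net$c,
    conv1_maps = cfg$net$conv1_maps, conv1_kernel = cfg$net$conv1_kernel,
    conv2_maps = cfg$net$conv2_maps, conv2_kernel = cfg$net$conv2_kernel,
    fc_hidden = cfg$net$fc_hidden, dropout_rate = cfg$net$dropout_rate))
  structure(list(net = net,
                 train = if (!is.null(cfg$train)) do.call(train_config, cfg$train[
                   c("base_lr", "momentum", "weight_decay", "lr_power",
                     "lr_gamma", "batch_size", "epochs", "seed", "augment_flip")]),
                 weights = readRDS(file.path(path, "weights.rds")),
                 loss = numeric(0), lr = numeric(0), fitted = NULL,
                 targets = NULL, meta = NULL, call = NULL),
            class = "vi_dnn")
}
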