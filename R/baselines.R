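# Ablation baselines: spectral (grayscale network), spatial (linear
# regression on the mean pixel) and temporal (stage hold-out splits).

#' Convert RGB plot samples to grayscale
#'
#' Per-pixel luma `0.299 R + 0.587 G + 0.114 B` (ITU-R BT.601). An
#' equal-weight mean of the three channels is available via `equal = TRUE`.
#'
#' @param x A `plot_samples` object with 3 channels, or an `H x W x 3` array.
#' @param equal Use weights (1/3, 1/3, 1/3) instead of luma weights.
#' @return The same kind of object with a single channel.
#' @export
#' @examples
#' to_grayscale(array(c(1, 0, 0), c(1, 1, 3)))  # 0.299
to_grayscale <- function(x, equal = FALSE) {
  wts <- if (equal) rep(1 / 3, 3) else c(0.299, 0.587, 0.114)
  if (inherits(x, "plot_samples")) {
    if (x$dim[3] != 3L) stop("samples must have 3 channels", call. = FALSE)
    npx <- x$dim[1] * x$dim[2]
    g <- wts[1] * x$x[seq_len(npx), , drop = FALSE] +
         wts[2] * x$x[npx + seq_len(npx), , drop = FALSE] +
         wts[3] * x$x[2L * npx + seq_len(npx), , drop = FALSE]
    return(structure(list(x = g, dim = c(x$dim[1:2], 1L), meta = x$meta,
                          excluded = x$excluded), class = "plot_samples"))
  }
  d <- dim(x)
  if (length(d) != 3L || d[3] != 3L)
    stop("input must have 3 channels", call. = FALSE)
  array(wts[1] * x[, , 1] + wts[2] * x[, , 2] + wts[3] * x[, , 3],
        c(d[1], d[2], 1L))
}

#' Spatial mean pixel of plot images
#'
#' Collapses each image to its per-channel spatial mean — the `1 x 1 x 3`
#' "spatially diminished" representation used by the linear baseline.
#'
#' @param x A `plot_samples` object or a single `H x W x C` array.
#' @return For `plot_samples`, an `n x C` matrix with columns `r_mean`,
#'   `g_mean`, `b_mean` (or `gray_mean`); for an array, a named vector.
#' @export
mean_pixel <- function(x) {
  ch_names <- function(C) if (C == 3L) c("r_mean", "g_mean", "b_mean") else
    paste0("ch", seq_len(C), "_mean")
  if (inherits(x, "plot_samples")) {
    if (ncol(x$x) == 0L) stop("empty sample set", call. = FALSE)
    npx <- x$dim[1] * x$dim[2]; C <- x$dim[3]
    out <- vapply(seq_len(C), function(ch)
      colMeans(x$x[(ch - 1L) * npx + seq_len(npx), , drop = FALSE]),
      numeric(ncol(x$x)))
    out <- matrix(out, ncol = C, dimnames = list(NULL, ch_names(C)))
    return(out)
  }
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || prod(d) == 0L)
    stop("input must be a non-empty H x W x C array", call. = FALSE)
  setNames(apply(x, 3, mean), ch_names(d[3]))
}

#' Linear-regression baseline on spatially diminished images
#'
#' Ordinary least squares of the plot vegetation index on the per-channel
#' spatial means, with intercept — the spatial ablation: all within-plot
#' texture is discarded and only the mean colour remains.
#'
#' @param samples A `plot_samples` object (3-channel) with VI targets.
#' @param targets Optional response overriding `samples$meta$target_vi`.
#' @return An object of class `vi_lm` wrapping the `lm` fit. Methods:
#'   `predict`, `coef`, `print`, `summary`, `residuals`, `fitted`.
#' @export
vi_lm <- function(samples, targets = NULL) {
  mp <- mean_pixel(samples)
  y <- targets %||% samples$meta$target_vi
  if (nrow(mp) < 4L)
    stop("need at least 4 samples to fit the linear baseline", call. = FALSE)
  df <- data.frame(mp, vi = y)
  fit <- lm(vi ~ ., data = df)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("rank-deficient design: collinear channel(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  structure(list(fit = fit, channels = colnames(mp), call = match.call()),
            class = "vi_lm")
}

#' @export
predict.vi_lm <- function(object, newdata, ...) {
  mp <- if (inherits(newdata, "plot_samples")) mean_pixel(newdata)
        else as.matrix(newdata)
  unname(predict(object$fit, newdata = as.data.frame(mp)))
}

#' @export
coef.vi_lm <- function(object, ...) coef(object$fit)

#' @export
residuals.vi_lm <- function(object, ...) residuals(object$fit)

#' @export
fitted.vi_lm <- function(object, ...) fitted(object$fit)

#' @export
print.vi_lm <- function(x, ...) {
  cat("Linear VI baseline (mean-pixel predictors)\n")
  print(coef(x$fit))
  invisible(x)
}

#' @export
summary.vi_lm <- function(object, ...) summary(object$fit)

#' Temporal hold-out splits (leave-one-stage-out)
#'
#' For each growth stage `s`, a split with training set "all samples of other
#' stages" and test set "all samples of stage `s`". Together the test sets
#' partition the data.
#'
#' @param x A `plot_samples` object, or a data frame with a `stage` column.
#' @param stages Optional subset of stages to build splits for (default all).
#' @return A list of splits, each a list with `stage`, `train` and `test`
#'   (integer indices into the samples).
#' @export
temporal_holdout_splits <- function(x, stages = NULL) {
  meta <- if (inherits(x, "plot_samples")) x$meta else as.data.frame(x)
  if (is.null(meta$stage)) stop("samples carry no stage labels", call. = FALSE)
  all_stages <- sort(unique(meta$stage))
  if (length(all_stages) < 2L)
    stop("temporal hold-out requires at least 2 stages", call. = FALSE)
  use <- stages %||% all_stages
  if (!all(use %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(use, all_stages), collapse = ", "),
         call. = FALSE)
  lapply(use, function(s) {
    test <- which(meta$stage == s)
    list(stage = s, train = setdiff(seq_len(nrow(meta)), test), test = test)
  })
}
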