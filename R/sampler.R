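#' Affine geotransform between world and pixel coordinates
#'
#' Maps continuous 0-based pixel coordinates `(px, py)` to world coordinates
#' via `world = origin + R(rotation) %*% (scale * pixel)` and back.
#'
#' @param origin World coordinates of pixel `(0, 0)`.
#' @param scale Metres per pixel along x and y; both components nonzero.
#' @param rotation Rotation in radians (default 0).
#' @return An object of class `geo_transform`.
#' @export
geo_transform <- function(origin = c(0, 0), scale = c(1, 1), rotation = 0) {
  if (length(origin) != 2 || length(scale) != 2)
    stop("`origin` and `scale` must have length 2", call. = FALSE)
  if (any(scale == 0) || any(!is.finite(scale)))
    stop("singular geotransform: scale components must be nonzero",
         call. = FALSE)
  structure(list(origin = as.numeric(origin), scale = as.numeric(scale),
                 rotation = as.numeric(rotation)), class = "geo_transform")
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Convert world coordinates to continuous pixel coordinates
#'
#' Exact affine inverse of the geotransform; rasterization to integer index
#' ranges is handled by [sample_plots()].
#'
#' @param pt Numeric vector `c(x, y)` or an `n x 2` matrix of world points.
#' @param gt A [geo_transform()].
#' @return Pixel coordinates with the shape of the input.
#' @export
#' @examples
#' gt <- geo_transform(origin = c(100, 200), scale = c(2, 2))
#' world_to_pixel(c(104, 206), gt)  # (2, 3)
world_to_pixel <- function(pt, gt) {
  one <- is.null(dim(pt))
  p <- if (one) matrix(pt, 1, 2) else as.matrix(pt)
  d <- sweep(p, 2, gt$origin)
  px <- d %*% rot_mat(-gt$rotation)   # rows: R(-theta) %*% d
  px <- sweep(px, 2, gt$scale, "/")
  if (one) drop(px) else px
}

#' @rdname world_to_pixel
#' @export
pixel_to_world <- function(pt, gt) {
  one <- is.null(dim(pt))
  p <- if (one) matrix(pt, 1, 2) else as.matrix(pt)
  w <- sweep(p, 2, gt$scale, "*") %*% rot_mat(gt$rotation)
  w <- sweep(w, 2, gt$origin, "+")
  if (one) drop(w) else w
}

#' Radiometric calibration against a reference panel
#'
#' Converts raw digital numbers to reflectance using the mean DN observed
#' over a calibration panel of known reflectance:
#' `reflectance = DN * panel_reflectance / panel_dn`, clipped to `[0, 1]`.
#'
#' @param dn Integer/numeric DN raster (matrix or vector), or a `dn_scene`.
#' @param panel_dn Mean DN over the panel region; must be positive. For a
#'   `dn_scene` input the default is the mean of its panel patch.
#' @param panel_reflectance Known panel reflectance in `(0, 1]`.
#' @return Reflectance with the shape of the input; for a `dn_scene`, a
#'   `field_scene` with calibrated bands.
#' @export
#' @examples
#' radiometric_scale(16384, panel_dn = 32768, panel_reflectance = 0.5)  # 0.25
radiometric_scale <- function(dn, panel_dn = NULL, panel_reflectance = NULL) {
  if (inherits(dn, "dn_scene")) {
    if (is.null(panel_dn)) panel_dn <- mean(dn$panel)
    if (is.null(panel_reflectance)) panel_reflectance <- dn$panel_reflectance
    bands <- lapply(dn$dn, radiometric_scale, panel_dn = panel_dn,
                    panel_reflectance = panel_reflectance)
    return(structure(list(bands = bands, geotransform = dn$geotransform,
                          grid = dn$grid, bay_id = dn$bay_id,
                          stage = dn$stage, truth = NULL),
                     class = "field_scene"))
  }
  if (is.null(panel_dn) || !is.finite(panel_dn) || panel_dn <= 0)
    stop("calibration error: `panel_dn` must be positive", call. = FALSE)
  out <- clip01(as.numeric(dn) * panel_reflectance / panel_dn)
  if (is.null(dim(dn))) out else matrix(out, nrow(dn), ncol(dn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-D resampling weights, rows = output pixels. Downscaling uses exact
# area-overlap averaging (preserves the mean); upscaling uses bilinear
# interpolation of pixel centres with edge clamping.
resize_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  if (n_out <= n_in) {
    r <- n_in / n_out
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * r; hi <- i * r
      j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        ov <- min(hi, j) - max(lo, j - 1)
        if (ov > 0) W[i, j] <- ov / r
      }
    }
  } else {
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * n_in / n_out - 0.5
      j <- floor(src); f <- src - j
      j0 <- min(max(j, 0), n_in - 1L); j1 <- min(j + 1, n_in - 1L)
      if (j < 0) { j0 <- j1 <- 0L; f <- 0 }
      W[i, j0 + 1L] <- W[i, j0 + 1L] + (1 - f)
      W[i, j1 + 1L] <- W[i, j1 + 1L] + f
    }
  }
  W
}

#' Resize an image to a target height and width
#'
#' Area-weighted averaging along downscaled axes (radiometry-preserving) and
#' bilinear interpolation along upscaled axes, applied separably.
#'
#' @param img A matrix or an `H x W x C` array with values in `[0, 1]`.
#' @param out_hw Integer `(height, width)` of the output.
#' @return The resized matrix or array.
#' @export
resize_image <- function(img, out_hw) {
  d <- dim(img)
  Wr <- resize_weights(d[1], out_hw[1])
  Wc <- t(resize_weights(d[2], out_hw[2]))
  if (length(d) == 2L) return(Wr %*% img %*% Wc)
  out <- array(0, c(out_hw[1], out_hw[2], d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% img[, , ch] %*% Wc
  out
}

#' Crop plot images and their vegetation-index targets from a scene
#'
#' For each rectangle of the plot grid: converts its world corners to pixel
#' coordinates, rasterizes to the half-open ranges
#' `[floor(min), floor(max))`, crops all five bands, computes the plot-mean
#' VI target on the native-resolution crop, and standardizes the RGB crop
#' (red, green, blue channels) to a fixed size. Rectangles that fall outside
#' the raster (fully or partially) are skipped and reported, not fatal.
#'
#' @param scene A `field_scene` (reflectance in `[0, 1]`).
#' @param grid A `plot_grid`; defaults to the scene's own grid.
#' @param index Vegetation index for the targets (see [vi_map()]).
#' @param params A [vi_params()].
#' @param out_hw Standardized `(height, width)` of the RGB crops; the default
#'   `c(15, 208)` matches long, thin single-row plots.
#' @return An object of class `plot_samples`: a list with `x` (numeric matrix,
#'   one vectorized `H x W x 3` image per column), `dim`, `meta` (data frame
#'   with `plot_id`, `bay`, `stage`, `target_vi`) and `excluded` (data frame
#'   of skipped plots with reasons).
#' @export
sample_plots <- function(scene, grid = scene$grid, index = "NDVI",
                         params = vi_params(), out_hw = c(15, 208)) {
  gt <- scene$geotransform
  H <- nrow(scene$bands[[1]]); W <- ncol(scene$bands[[1]])
  n <- nrow(grid)
  npx_out <- out_hw[1] * out_hw[2] * 3L
  x <- matrix(NA_real_, npx_out, n)
  keep <- logical(n)
  target <- numeric(n)
  reason <- character(n)
  Wr <- Wc <- NULL; crop_dim <- c(NA_integer_, NA_integer_)
  for (k in seq_len(n)) {
    corners <- rbind(c(grid$min_x[k], grid$min_y[k]),
                     c(grid$max_x[k], grid$max_y[k]))
    px <- world_to_pixel(corners, gt)
    xs <- sort(px[, 1]); ys <- sort(px[, 2])
    x0 <- raster_floor(xs[1]); x1 <- raster_floor(xs[2])
    y0 <- raster_floor(ys[1]); y1 <- raster_floor(ys[2])
    if (x0 < 0 || y0 < 0 || x1 > W || y1 > H) {
      reason[k] <- "outside raster extent"; next
    }
    if (x1 <= x0 || y1 <= y0) { reason[k] <- "empty crop"; next }
    rows <- (y0 + 1):y1; cols <- (x0 + 1):x1
    crop <- lapply(scene$bands, function(b) b[rows, cols, drop = FALSE])
    target[k] <- plot_mean_vi(vi_map(crop, index, params))
    # resampling weights are shared across plots of identical footprint
    if (is.null(Wr) || !identical(crop_dim, c(length(rows), length(cols)))) {
      crop_dim <- c(length(rows), length(cols))
      Wr <- resize_weights(crop_dim[1], out_hw[1])
      Wc <- t(resize_weights(crop_dim[2], out_hw[2]))
    }
    rgb <- vapply(c("red", "green", "blue"),
                  function(b) Wr %*% crop[[b]] %*% Wc,
                  matrix(0, out_hw[1], out_hw[2]))
    x[, k] <- as.vector(rgb)
    keep[k] <- TRUE
  }
  if (any(!keep))
    warning(sprintf("%d plot(s) skipped: %s", sum(!keep),
                    paste(unique(reason[!keep]), collapse = "; ")),
            call. = FALSE)
  meta <- data.frame(plot_id = grid$plot_id[keep], bay = grid$bay[keep],
                     stage = scene$stage, target_vi = target[keep],
                     stringsAsFactors = FALSE)
  structure(list(x = x[, keep, drop = FALSE],
                 dim = c(as.integer(out_hw), 3L), meta = meta,
                 excluded = data.frame(plot_id = grid$plot_id[!keep],
                                       reason = reason[!keep],
                                       stringsAsFactors = FALSE)),
            class = "plot_samples")
}

#' @export
print.plot_samples <- function(x, ...) {
  cat(sprintf("%d plot samples of %d x %d x %d (%d excluded)\n",
              ncol(x$x), x$dim[1], x$dim[2], x$dim[3], nrow(x$excluded)))
  if (nrow(x$meta)) {
    cat(sprintf("  bays: %s; stages: %s; target VI range [%.4f, %.4f]\n",
                paste(unique(x$meta$bay), collapse = ", "),
                paste(sort(unique(x$meta$stage)), collapse = ", "),
                min(x$meta$target_vi), max(x$meta$target_vi)))
  }
  invisible(x)
}

#' @export
`[.plot_samples` <- function(x, i) {
  structure(list(x = x$x[, i, drop = FALSE], dim = x$dim,
                 meta = x$meta[i, , drop = FALSE],
                 excluded = x$excluded[0, , drop = FALSE]),
            class = "plot_samples")
}

#' @export
length.plot_samples <- function(x) ncol(x$x)

#' Combine plot-sample sets from several scenes
#'
#' @param ... `plot_samples` objects with identical image dimensions.
#' @return A single `plot_samples` object.
#' @export
bind_samples <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "plot_samples")) parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, TRUE, "plot_samples")))
  d <- parts[[1]]$dim
  if (!all(vapply(parts, function(p) identical(p$dim, d), TRUE)))
    stop("sample sets have differing image dimensions", call. = FALSE)
  structure(list(x = do.call(cbind, lapply(parts, `[[`, "x")), dim = d,
                 meta = do.call(rbind, lapply(parts, `[[`, "meta")),
                 excluded = do.call(rbind, lapply(parts, `[[`, "excluded"))),
            class = "plot_samples")
}

#' Extract one sample's image as an array
#'
#' @param samples A `plot_samples` object.
#' @param i Sample index.
#' @return An `H x W x C` array.
#' @export
sample_image <- function(samples, i) {
  array(samples$x[, i], samples$dim)
}

#' Read and write plot grids as CSV
#'
#' Columns: `plot_id`, `bay`, `range`, `row`, `min_x`, `min_y`, `max_x`,
#' `max_y` (world units).
#'
#' @param grid A `plot_grid` data frame.
#' @param path CSV path.
#' @export
write_plot_grid <- function(grid, path) {
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plot_grid
#' @export
read_plot_grid <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "bay", "range", "row", "min_x", "min_y", "max_x", "max_y")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("grid CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(g$max_x <= g$min_x | g$max_y <= g$min_y))
    stop("grid rectangles must have positive area", call. = FALSE)
  class(g) <- c("plot_grid", "data.frame")
  g
}

#' Ground-reference plot selection
#'
#' Emulates the hand-held sensor protocol: within each bay, a fixed number of
#' survey lines (ranges) is selected at evenly spaced positions, and a fixed
#' number of consecutive plots behind each line is marked as
#' ground-referenced (default 2 lines x 12 plots = 24 per bay).
#'
#' @param grid A `plot_grid` covering one or more bays.
#' @param lines Survey lines per bay.
#' @param per_line Plots measured behind each line.
#' @return The subset of `grid` containing the reference plots.
#' @export
ground_reference_plots <- function(grid, lines = 2L, per_line = 12L) {
  pick <- function(g) {
    ranges <- sort(unique(g$range))
    sel <- ranges[unique(pmax(1L, round(seq(1, length(ranges),
                                            length.out = lines))))]
    do.call(rbind, lapply(sel, function(r) {
      gr <- g[g$range == r, , drop = FALSE]
      gr[order(gr$row), , drop = FALSE][seq_len(min(per_line, nrow(gr))), ,
                                        drop = FALSE]
    }))
  }
  out <- do.call(rbind, lapply(split(as.data.frame(grid), grid$bay), pick))
  rownames(out) <- NULL
  class(out) <- c("plot_grid", "data.frame")
  out
}
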