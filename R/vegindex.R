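#' Coefficients of the soil- and atmosphere-corrected vegetation indices
#'
#' SAVI's soil-adjustment factor `L` and EVI's gain and aerosol-resistance
#' coefficients. The defaults are the literature's standard constants
#' (SAVI `L = 0.5`; EVI `G = 2.5`, `c1 = 6`, `c2 = 7.5`, `L = 1`).
#'
#' @param savi_L Soil-adjustment factor, unitless, `>= 0`.
#' @param evi_G EVI gain.
#' @param evi_c1,evi_c2 Red and blue aerosol-resistance coefficients.
#' @param evi_L EVI canopy background factor.
#' @return An object of class `vi_params`.
#' @export
vi_params <- function(savi_L = 0.5, evi_G = 2.5, evi_c1 = 6, evi_c2 = 7.5,
                      evi_L = 1) {
  for (nm in c("savi_L", "evi_G", "evi_c1", "evi_c2", "evi_L"))
    stopifnot_number(get(nm), nm)
  if (savi_L < 0) stop("`savi_L` must be >= 0", call. = FALSE)
  structure(list(savi_L = savi_L, evi_G = evi_G, evi_c1 = evi_c1,
                 evi_c2 = evi_c2, evi_L = evi_L), class = "vi_params")
}

VI_INDICES <- c("NDVI", "GNDVI", "RENDVI", "SAVI", "EVI")

vi_required_bands <- function(index) {
  switch(index,
    NDVI = c("nir", "red"), GNDVI = c("nir", "green"),
    RENDVI = c("nir", "rededge"), SAVI = c("nir", "red"),
    EVI = c("nir", "red", "blue"),
    stop("unknown vegetation index: ", index, call. = FALSE))
}

#' Per-pixel vegetation-index map
#'
#' Evaluates one of the five standard index formulas element-wise over the
#' reflectance bands of a scene or plot crop:
#' \deqn{NDVI = (NIR - Red)/(NIR + Red)}
#' \deqn{GNDVI = (NIR - Green)/(NIR + Green)}
#' \deqn{RENDVI = (NIR - RedEdge)/(NIR + RedEdge)}
#' \deqn{SAVI = (1 + L)(NIR - Red)/(NIR + Red + L)}
#' \deqn{EVI = G (NIR - Red)/(NIR + c_1 Red - c_2 Blue + L)}
#' Pixels whose denominator is exactly zero are flagged invalid rather than
#' propagated as non-finite values.
#'
#' @param x A `field_scene`, or a named list/environment of band matrices (or
#'   vectors) containing at least the bands the index needs.
#' @param index One of `"NDVI"`, `"GNDVI"`, `"RENDVI"`, `"SAVI"`, `"EVI"`.
#' @param params A [vi_params()] object (used by SAVI and EVI).
#' @return An object of class `vi_map`: list with `values` (invalid pixels are
#'   `NA`), `index`, and logical `valid_mask`.
#' @export
#' @examples
#' vi_map(list(nir = 0.5, red = 0.1), "NDVI")$values  # 0.4 / 0.6
vi_map <- function(x, index = "NDVI", params = vi_params()) {
  index <- toupper(index)
  if (!index %in% VI_INDICES)
    stop("unknown vegetation index: ", index, call. = FALSE)
  bands <- if (inherits(x, "field_scene")) x$bands else x
  need <- vi_required_bands(index)
  miss <- setdiff(need, names(bands))
  if (length(miss))
    stop("missing band(s) for ", index, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  b <- bands
  nd <- switch(index,
    NDVI   = list(b$nir - b$red, b$nir + b$red),
    GNDVI  = list(b$nir - b$green, b$nir + b$green),
    RENDVI = list(b$nir - b$rededge, b$nir + b$rededge),
    SAVI   = list((1 + params$savi_L) * (b$nir - b$red),
                  b$nir + b$red + params$savi_L),
    EVI    = list(params$evi_G * (b$nir - b$red),
                  b$nir + params$evi_c1 * b$red - params$evi_c2 * b$blue +
                    params$evi_L)
  )
  valid <- nd[[2]] != 0
  values <- nd[[1]]
  values[valid] <- nd[[1]][valid] / nd[[2]][valid]
  values[!valid] <- NA_real_
  structure(list(values = values, index = index, valid_mask = valid),
            class = "vi_map")
}

#' @export
print.vi_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("%s map: %d px (%d invalid), range [%.4f, %.4f], mean %.4f\n",
              x$index, length(x$values), sum(!x$valid_mask),
              min(v), max(v), mean(v)))
  invisible(x)
}

#' Plot-mean vegetation index (the mean-pooled regression target)
#'
#' Arithmetic mean of the per-pixel index values over the valid mask. This is
#' the spatial mean pooling of the per-pixel VI map — deliberately the mean of
#' per-pixel VI, not the VI of mean reflectance; the two differ on mixed
#' soil/vegetation pixels.
#'
#' @param map A `vi_map`.
#' @return A single numeric value.
#' @export
plot_mean_vi <- function(map) {
  if (!inherits(map, "vi_map")) stop("`map` must be a vi_map", call. = FALSE)
  v <- map$values[map$valid_mask]
  if (!length(v))
    stop("empty plot: no valid pixels to average", call. = FALSE)
  mean(v)
}
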