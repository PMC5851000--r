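#' Built-in spectral presets for the field simulator
#'
#' Returns per-class reflectance spectra over the five camera bands
#' (blue, green, red, red-edge, NIR) for bare soil, healthy vegetation and
#' senescent vegetation.
#'
#' The `"default"` preset is a generic high-NIR/low-red healthy canopy over a
#' brighter soil background. The `"ablation"` preset is constructed for the
#' spectral/spatial ablation experiments: the three classes share the same
#' luma (0.299 R + 0.587 G + 0.114 B), so a grayscale rendering carries almost
#' no class information, and the senescent visible spectrum lies on the
#' soil--vegetation line in RGB space (a metamer of a partial canopy) while
#' its NIR reflectance does not. Under that preset the plot-mean VI is not a
#' linear function of the plot's mean RGB colour, which is exactly the regime
#' where spatial texture carries the missing information.
#'
#' @param preset `"default"` or `"ablation"`.
#' @return A list with elements `soil`, `veg`, `sen`, each a named numeric
#'   vector over `c("blue","green","red","rededge","nir")`.
#' @export
#' @examples
#' vi_spectra("default")$veg
vi_spectra <- function(preset = c("default", "ablation")) {
  preset <- match.arg(preset)
  mk <- function(v) setNames(v, BAND_NAMES)
  switch(preset,
    default = list(
      soil = mk(c(0.10, 0.15, 0.20, 0.25, 0.30)),
      veg  = mk(c(0.04, 0.08, 0.05, 0.30, 0.50)),
      sen  = mk(c(0.15, 0.20, 0.25, 0.28, 0.30))
    ),
    ablation = list(
      # iso-luminant classes; sen visible = soil + 0.4 * (veg - soil)
      soil = mk(c(0.1020, 0.110, 0.180, 0.20, 0.22)),
      veg  = mk(c(0.0560, 0.180, 0.060, 0.30, 0.50)),
      sen  = mk(c(0.0836, 0.138, 0.132, 0.22, 0.18))
    )
  )
}

#' Configuration for the synthetic multispectral field simulator
#'
#' Describes a wheat-style breeding trial: `n_bays` spatially distinct bays,
#' each holding `plots_per_bay` single-row plots imaged at `n_stages` time
#' points across the season. Vegetation cover rises and then senesces
#' according to `cover_curve` and `senescence_curve`; each plot additionally
#' carries a persistent random deviation from the stage curves so that plots
#' within a stage differ (as breeding-trial entries do).
#'
#' @param n_bays Number of bays (spatial blocks).
#' @param plots_per_bay Plots per bay.
#' @param n_stages Number of growth stages (imaging sessions).
#' @param plot_px Height and width of a plot footprint in raster pixels.
#' @param gsd Ground sampling distance, metres per pixel.
#' @param spectra A list as returned by [vi_spectra()].
#' @param cover_curve Per-stage expected vegetation cover fraction in `[0,1]`.
#' @param senescence_curve Per-stage expected fraction of vegetation pixels
#'   that are senescent, in `[0,1]`.
#' @param cover_jitter,sen_jitter Scale of the persistent per-plot deviation
#'   of cover/senescence from the stage curve. The deviation of a plot with
#'   stage value `p` has standard deviation `2 * jitter * sqrt(p * (1 - p))`,
#'   so it vanishes at `p = 0` and `p = 1`.
#' @param noise_sd Per-pixel, per-band Gaussian sensor noise in reflectance
#'   units (applied before clipping to `[0,1]`).
#' @param panel_reflectance Reflectance of the calibration panel, in `(0,1]`.
#' @param dn_max Integer ceiling of the digital-number encoding (16-bit: 65535).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param bay_ids Optional character labels for bays (default `"R40"`, ...).
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_bays = 2, plots_per_bay = 8, n_stages = 3,
#'                     plot_px = c(4, 20))
#' cfg$cover_curve
synth_config <- function(n_bays = 3,
                         plots_per_bay = 576,
                         n_stages = 7,
                         plot_px = c(8, 200),
                         gsd = 0.02,
                         spectra = vi_spectra("default"),
                         cover_curve = NULL,
                         senescence_curve = NULL,
                         cover_jitter = 0.25,
                         sen_jitter = 0.25,
                         noise_sd = 0.01,
                         panel_reflectance = 0.5,
                         dn_max = 65535L,
                         seed = 1L,
                         bay_ids = NULL) {
  if (is.null(cover_curve))
    cover_curve <- default_stage_curve(n_stages, "cover")
  if (is.null(senescence_curve))
    senescence_curve <- default_stage_curve(n_stages, "senescence")
  stopifnot_number(n_bays, "n_bays", 1); stopifnot_number(plots_per_bay, "plots_per_bay", 1)
  stopifnot_number(n_stages, "n_stages", 1)
  stopifnot_number(gsd, "gsd", 1e-6); stopifnot_number(noise_sd, "noise_sd", 0)
  stopifnot_number(panel_reflectance, "panel_reflectance", 1e-6, 1)
  if (!is.numeric(dn_max) || dn_max <= 0)
    stop("`dn_max` must be a positive integer", call. = FALSE)
  if (length(plot_px) != 2L || any(plot_px < 1))
    stop("`plot_px` must be (height, width) in pixels, both >= 1", call. = FALSE)
  if (length(cover_curve) != n_stages || length(senescence_curve) != n_stages)
    stop("`cover_curve` and `senescence_curve` must have length `n_stages`",
         call. = FALSE)
  if (any(cover_curve < 0 | cover_curve > 1) ||
      any(senescence_curve < 0 | senescence_curve > 1))
    stop("stage curves must lie in [0, 1]", call. = FALSE)
  for (cls in c("soil", "veg", "sen")) {
    sp <- spectra[[cls]]
    if (is.null(sp) || length(sp) != 5L || any(sp < 0 | sp > 1))
      stop(sprintf("spectra$%s must be 5 reflectances in [0, 1]", cls),
           call. = FALSE)
  }
  if (spectra$veg[["nir"]] <= spectra$veg[["red"]])
    stop("vegetation spectrum must have NIR > red", call. = FALSE)
  if (is.null(bay_ids)) bay_ids <- paste0("R", 39L + seq_len(n_bays))
  if (length(bay_ids) != n_bays) stop("need one bay id per bay", call. = FALSE)
  structure(list(
    n_bays = as.integer(n_bays), plots_per_bay = as.integer(plots_per_bay),
    n_stages = as.integer(n_stages), plot_px = as.integer(plot_px), gsd = gsd,
    spectra = lapply(spectra[c("soil", "veg", "sen")], function(s) setNames(as.numeric(s), BAND_NAMES)),
    cover_curve = as.numeric(cover_curve),
    senescence_curve = as.numeric(senescence_curve),
    cover_jitter = cover_jitter, sen_jitter = sen_jitter,
    noise_sd = noise_sd, panel_reflectance = panel_reflectance,
    dn_max = as.integer(dn_max), seed = as.integer(seed), bay_ids = bay_ids
  ), class = "synth_config")
}

# Season trajectories: cover rises to a plateau then thins slightly;
# senescence is negligible early and dominates the terminal stage.
default_stage_curve <- function(n_stages, what = c("cover", "senescence")) {
  what <- match.arg(what)
  t <- seq(0, 1, length.out = n_stages)
  if (what == "cover") {
    0.9 * (1 / (1 + exp(-8 * (t - 0.3)))) * (1 - 0.1 * pmax(t - 0.7, 0) / 0.3)
  } else {
    0.8 * pmax(t - 0.55, 0)^2 / 0.45^2
  }
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic field configuration\n")
  cat(sprintf("  layout: %d bays x %d plots x %d stages (plot %d x %d px, GSD %.3g m)\n",
              x$n_bays, x$plots_per_bay, x$n_stages, x$plot_px[1], x$plot_px[2], x$gsd))
  cat(sprintf("  cover curve:      %s\n", paste(sprintf("%.2f", x$cover_curve), collapse = " ")))
  cat(sprintf("  senescence curve: %s\n", paste(sprintf("%.2f", x$senescence_curve), collapse = " ")))
  cat(sprintf("  noise sd %.3g, panel %.2f, dn_max %d, seed %d\n",
              x$noise_sd, x$panel_reflectance, x$dn_max, x$seed))
  invisible(x)
}

# Bay-internal layout: plots tile a near-square grid of `ranges` columns and
# `rows` rows (576 plots -> 12 ranges x 48 rows, the trial geometry).
bay_layout <- function(cfg) {
  p <- cfg$plots_per_bay
  n_ranges <- max(1L, as.integer(floor(sqrt(p / 4))))
  n_rows <- as.integer(ceiling(p / n_ranges))
  gap_x <- max(4L, as.integer(round(cfg$plot_px[2] * 0.05)))
  gap_y <- max(2L, as.integer(round(cfg$plot_px[1] * 0.5)))
  margin <- 8L
  list(n_ranges = n_ranges, n_rows = n_rows, gap_x = gap_x, gap_y = gap_y,
       margin = margin,
       width  = 2L * margin + n_ranges * (cfg$plot_px[2] + gap_x) - gap_x,
       height = 2L * margin + n_rows * (cfg$plot_px[1] + gap_y) - gap_y)
}

#' Plot grid of one synthetic bay, in world coordinates
#'
#' @param cfg A [synth_config()].
#' @param bay Bay label (one of `cfg$bay_ids`) or bay index.
#' @return A `plot_grid` data frame with columns `plot_id`, `bay`, `range`,
#'   `row`, `min_x`, `min_y`, `max_x`, `max_y` (world metres).
#' @export
field_grid <- function(cfg, bay) {
  bi <- bay_index(cfg, bay)
  lay <- bay_layout(cfg)
  gt <- bay_geotransform(cfg, bi)
  k <- seq_len(cfg$plots_per_bay) - 1L
  rng <- k %/% lay$n_rows            # range (column block) index, 0-based
  row <- k %% lay$n_rows             # row within range, 0-based
  px_x0 <- lay$margin + rng * (cfg$plot_px[2] + lay$gap_x)
  px_y0 <- lay$margin + row * (cfg$plot_px[1] + lay$gap_y)
  w0 <- pixel_to_world(cbind(px_x0, px_y0), gt)
  w1 <- pixel_to_world(cbind(px_x0 + cfg$plot_px[2], px_y0 + cfg$plot_px[1]), gt)
  g <- data.frame(
    plot_id = sprintf("%s_p%04d", cfg$bay_ids[bi], k + 1L),
    bay = cfg$bay_ids[bi], range = rng + 1L, row = row + 1L,
    min_x = pmin(w0[, 1], w1[, 1]), min_y = pmin(w0[, 2], w1[, 2]),
    max_x = pmax(w0[, 1], w1[, 1]), max_y = pmax(w0[, 2], w1[, 2]),
    stringsAsFactors = FALSE
  )
  class(g) <- c("plot_grid", "data.frame")
  g
}

bay_index <- function(cfg, bay) {
  if (is.numeric(bay)) {
    bi <- as.integer(bay)
  } else {
    bi <- match(as.character(bay), cfg$bay_ids)
  }
  if (is.na(bi) || bi < 1L || bi > cfg$n_bays)
    stop("unknown bay: ", bay, call. = FALSE)
  bi
}

# Each bay occupies its own strip of world space, side by side.
bay_geotransform <- function(cfg, bi) {
  lay <- bay_layout(cfg)
  origin_x <- (bi - 1L) * (lay$width * cfg$gsd * 1.25)
  geo_transform(origin = c(origin_x, 0), scale = c(cfg$gsd, cfg$gsd))
}

# Persistent per-plot deviations of cover and senescence from the stage
# curves; a function of (seed, bay) only, so a plot keeps its character
# across the season.
plot_effects <- function(cfg, bi) {
  with_seed(substream_seed(cfg$seed, "plot-effects", cfg$bay_ids[bi]), {
    data.frame(z_cover = rnorm(cfg$plots_per_bay),
               z_sen = rnorm(cfg$plots_per_bay))
  })
}

#' Generate one synthetic field scene
#'
#' Renders the five-band reflectance raster of one bay at one growth stage.
#' Within each plot footprint, pixels are drawn independently as vegetation
#' with the plot's cover probability; vegetation pixels are senescent with the
#' plot's senescence probability. Everything else is soil. Zero-mean Gaussian
#' noise of sd `noise_sd` is added per band and the raster is clipped to
#' `[0,1]`. The result is deterministic given `(cfg$seed, bay, stage)`.
#'
#' @param cfg A [synth_config()].
#' @param bay Bay label or index.
#' @param stage Growth-stage index in `1:cfg$n_stages`.
#' @return An object of class `field_scene`: a list with `bands` (named list
#'   of 5 matrices), `geotransform`, `grid`, `bay_id`, `stage`, and a `truth`
#'   data frame with the realized per-plot class fractions and the plot's
#'   cover/senescence probabilities.
#' @export
#' @examples
#' cfg <- synth_config(n_bays = 1, plots_per_bay = 4, n_stages = 2,
#'                     plot_px = c(4, 12), noise_sd = 0)
#' sc <- generate_field(cfg, "R40", 2)
#' names(sc$bands)
generate_field <- function(cfg, bay, stage) {
  if (!inherits(cfg, "synth_config")) stop("`cfg` must be a synth_config")
  bi <- bay_index(cfg, bay)
  stage <- as.integer(stage)
  if (is.na(stage) || stage < 1L || stage > cfg$n_stages)
    stop(sprintf("invalid stage index %s (must be in 1..%d)", stage, cfg$n_stages),
         call. = FALSE)
  lay <- bay_layout(cfg)
  gt <- bay_geotransform(cfg, bi)
  grid <- field_grid(cfg, bi)
  eff <- plot_effects(cfg, bi)

  c0 <- cfg$cover_curve[stage]
  s0 <- cfg$senescence_curve[stage]
  cover <- clip01(c0 + 2 * cfg$cover_jitter * sqrt(c0 * (1 - c0)) * eff$z_cover)
  sen   <- clip01(s0 + 2 * cfg$sen_jitter   * sqrt(s0 * (1 - s0)) * eff$z_sen)

  H <- lay$height; W <- lay$width
  sp <- cfg$spectra
  # class raster: 0 soil, 1 healthy vegetation, 2 senescent vegetation
  cls <- matrix(0L, H, W)
  n_veg <- n_sen <- integer(cfg$plots_per_bay)
  npx_plot <- cfg$plot_px[1] * cfg$plot_px[2]
  with_seed(substream_seed(cfg$seed, "scene", cfg$bay_ids[bi], stage), {
    px0 <- world_to_pixel(cbind(grid$min_x, grid$min_y), gt)
    for (k in seq_len(cfg$plots_per_bay)) {
      x0 <- as.integer(raster_floor(px0[k, 1]))
      y0 <- as.integer(raster_floor(px0[k, 2]))
      is_veg <- runif(npx_plot) < cover[k]
      is_sen <- is_veg & (runif(npx_plot) < sen[k])
      ck <- matrix(0L, cfg$plot_px[1], cfg$plot_px[2])
      ck[is_veg] <- 1L; ck[is_sen] <- 2L
      cls[y0 + seq_len(cfg$plot_px[1]), x0 + seq_len(cfg$plot_px[2])] <- ck
      n_veg[k] <- sum(is_veg & !is_sen); n_sen[k] <- sum(is_sen)
    }
    bands <- lapply(BAND_NAMES, function(b) {
      base <- matrix(sp$soil[[b]], H, W)
      base[cls == 1L] <- sp$veg[[b]]
      base[cls == 2L] <- sp$sen[[b]]
      if (cfg$noise_sd > 0)
        base <- base + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
      clip01(base)
    })
  })
  names(bands) <- BAND_NAMES
  truth <- data.frame(
    plot_id = grid$plot_id, cover = cover, senescence = sen,
    f_veg = n_veg / npx_plot, f_sen = n_sen / npx_plot,
    f_soil = 1 - (n_veg + n_sen) / npx_plot, stringsAsFactors = FALSE
  )
  structure(list(bands = bands, geotransform = gt, grid = grid,
                 bay_id = cfg$bay_ids[bi], stage = stage, truth = truth),
            class = "field_scene")
}

#' @export
print.field_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("Field scene: bay %s, stage %d, %d x %d px, %d plots\n",
              x$bay_id, x$stage, d[1], d[2], nrow(x$grid)))
  invisible(x)
}

#' Encode a reflectance scene as raw 16-bit digital numbers
#'
#' Applies an (arbitrary, per-scene) sensor gain and quantizes reflectance to
#' integer digital numbers `DN = round(reflectance * dn_max * gain)`, together
#' with a rendered calibration-panel patch of known reflectance. The panel
#' patch carries sub-DN dither so that its mean recovers the true panel DN to
#' well below one count; [radiometric_scale()] inverts the encoding up to
#' rounding.
#'
#' @param scene A `field_scene` with reflectances in `[0,1]`.
#' @param cfg The [synth_config()] that produced it.
#' @param gain Optional sensor gain in `(0.5, 1]`; by default drawn
#'   deterministically from the scene's sub-stream in `[0.6, 0.95]`.
#' @param panel_px Side length of the square panel patch.
#' @return An object of class `dn_scene`: integer `dn` rasters per band, the
#'   integer `panel` patch, `panel_reflectance`, and scene metadata.
#' @export
encode_dn <- function(scene, cfg, gain = NULL, panel_px = 32L) {
  if (cfg$dn_max <= 0) stop("`dn_max` must be positive", call. = FALSE)
  rng_seed <- substream_seed(cfg$seed, "dn", scene$bay_id, scene$stage)
  if (is.null(gain)) {
    gain <- with_seed(rng_seed, runif(1, 0.6, 0.95))
  }
  if (gain <= 0.5 || gain > 1)
    stop("`gain` must lie in (0.5, 1] so quantization stays below 1/dn_max",
         call. = FALSE)
  M <- as.double(cfg$dn_max)
  dn <- lapply(scene$bands, function(b) {
    m <- round(b * M * gain)
    storage.mode(m) <- "integer"
    m
  })
  panel_true <- cfg$panel_reflectance * M * gain
  panel <- with_seed(substream_seed(rng_seed, "panel"), {
    matrix(as.integer(pmin(pmax(round(panel_true +
             runif(panel_px^2, -0.5, 0.5)), 0), cfg$dn_max)),
           panel_px, panel_px)
  })
  structure(list(dn = dn, panel = panel,
                 panel_reflectance = cfg$panel_reflectance,
                 dn_max = cfg$dn_max, gain = gain,
                 geotransform = scene$geotransform, grid = scene$grid,
                 bay_id = scene$bay_id, stage = scene$stage),
            class = "dn_scene")
}

#' Write / read a field scene as a multi-page TIFF with text sidecars
#'
#' Bands are written as 32-bit float TIFF pages in the order blue, green,
#' red, red-edge, NIR; the geotransform and labels go to a YAML sidecar and
#' the plot grid to a CSV next to the raster.
#'
#' @param scene A `field_scene`.
#' @param path Output path for the `.tif` file.
#' @return `write_scene` returns `path` invisibly; `read_scene` returns a
#'   `field_scene` (without the simulator `truth` table).
#' @export
write_scene <- function(scene, path) {
  tiff::writeTIFF(unname(scene$bands), path, bits.per.sample = 32L)
  gt <- scene$geotransform
  meta <- list(bands = BAND_NAMES,
               geotransform = list(origin = as.numeric(gt$origin),
                                   scale = as.numeric(gt$scale),
                                   rotation = gt$rotation),
               bay_id = scene$bay_id, stage = scene$stage)
  writeLines(yaml::as.yaml(meta), sub("\\.tif{1,2}$", ".yaml", path))
  write_plot_grid(scene$grid, sub("\\.tif{1,2}$", "_grid.csv", path))
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sub("\\.tif{1,2}$", ".yaml", path))
  grid <- read_plot_grid(sub("\\.tif{1,2}$", "_grid.csv", path))
  bands <- setNames(pages, meta$bands)
  gt <- geo_transform(origin = unlist(meta$geotransform$origin),
                      scale = unlist(meta$geotransform$scale),
                      rotation = meta$geotransform$rotation)
  structure(list(bands = bands, geotransform = gt, grid = grid,
                 bay_id = meta$bay_id, stage = meta$stage, truth = NULL),
            class = "field_scene")
}
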