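test_that("world/pixel conversion is the exact affine inverse", {
  gt_id <- geo_transform()
  expect_equal(world_to_pixel(c(10, 5), gt_id), c(10, 5))
  gt <- geo_transform(origin = c(100, 200), scale = c(2, 2))
  expect_equal(world_to_pixel(c(104, 206), gt), c(2, 3))
  gtr <- geo_transform(origin = c(3, -1), scale = c(0.5, 2), rotation = 0.3)
  set.seed(1)
  px <- matrix(runif(20, -50, 50), 10, 2)
  expect_equal(world_to_pixel(pixel_to_world(px, gtr), gtr), px,
               tolerance = 1e-9)
  expect_error(geo_transform(scale = c(0, 1)), "singular")
})

test_that("radiometric scaling matches the panel-ratio formula", {
  expect_equal(radiometric_scale(16384, 32768, 0.5), 0.25)
  expect_equal(radiometric_scale(0, 32768, 0.5), 0)
  expect_equal(radiometric_scale(32768, 32768, 0.37), 0.37)
  expect_error(radiometric_scale(100, 0, 0.5), "calibration")
  expect_error(radiometric_scale(100, -3, 0.5), "calibration")
  m <- matrix(c(0L, 16384L, 32768L, 65535L), 2)
  out <- radiometric_scale(m, 32768, 0.5)
  expect_true(is.matrix(out))
  expect_equal(out[2, 2], 65535 * 0.5 / 32768)
  expect_equal(radiometric_scale(70000, 32768, 0.5), 1)  # clipped to [0, 1]
})

test_that("area-average downscaling preserves channel means exactly", {
  set.seed(3)
  img <- array(runif(30 * 416 * 3), c(30, 416, 3))  # 2x the target size
  small <- resize_image(img, c(15, 208))
  for (ch in 1:3)
    expect_equal(mean(small[, , ch]), mean(img[, , ch]), tolerance = 1e-6)
})

test_that("resizing a constant image is constant (up and down)", {
  img <- array(0.37, c(8, 100, 3))
  up <- resize_image(img, c(15, 208))
  expect_equal(dim(up), c(15, 208, 3))
  expect_equal(range(up), c(0.37, 0.37), tolerance = 1e-12)
  down <- resize_image(array(0.2, c(45, 624, 3)), c(15, 208))
  expect_equal(range(down), c(0.2, 0.2), tolerance = 1e-12)
})

make_test_scene <- function(noise_sd = 0, plots = 4) {
  cfg <- synth_config(n_bays = 1, plots_per_bay = plots, n_stages = 2,
                      plot_px = c(6, 40), noise_sd = noise_sd, seed = 9)
  generate_field(cfg, 1, 2)
}

test_that("sample_plots crops one standardized sample per in-bounds rect", {
  sc <- make_test_scene()
  s <- sample_plots(sc)
  expect_s3_class(s, "plot_samples")
  expect_equal(length(s), nrow(sc$grid))
  expect_equal(s$dim, c(15L, 208L, 3L))
  expect_equal(nrow(s$x), 15 * 208 * 3)
  expect_equal(nrow(s$excluded), 0)
  img <- sample_image(s, 1)
  expect_equal(dim(img), c(15, 208, 3))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("rects outside the raster are skipped and reported", {
  sc <- make_test_scene(plots = 4)
  grid <- sc$grid
  grid$min_x[2] <- grid$min_x[2] - 1e4   # push one rect off the raster
  expect_warning(s <- sample_plots(sc, grid = grid), "skipped")
  expect_equal(length(s), 3)
  expect_equal(nrow(s$excluded), 1)
  expect_match(s$excluded$reason, "outside")
})

test_that("constant scenes give constant crops with the constant's index value", {
  cfg <- synth_config(n_bays = 1, plots_per_bay = 2, n_stages = 1,
                      plot_px = c(6, 40), noise_sd = 0,
                      cover_curve = 1, senescence_curve = 0, seed = 2)
  sc <- generate_field(cfg, 1, 1)
  s <- sample_plots(sc)
  veg <- cfg$spectra$veg
  expect_equal(max(abs(s$x - rep(veg[c("red", "green", "blue")],
                                 each = 15 * 208))), 0, tolerance = 1e-12)
  expect_equal(s$meta$target_vi,
               rep(unname((veg["nir"] - veg["red"]) / (veg["nir"] + veg["red"])), 2))
})

test_that("the VI target comes from the native crop, not the resized image", {
  sc <- make_test_scene()
  s1 <- sample_plots(sc, out_hw = c(15, 208))
  s2 <- sample_plots(sc, out_hw = c(6, 40))   # no resampling at all
  s3 <- sample_plots(sc, out_hw = c(3, 20))   # pure downscale
  expect_equal(s1$meta$target_vi, s2$meta$target_vi)
  expect_equal(s1$meta$target_vi, s3$meta$target_vi)
})

test_that("plot grids survive a CSV round trip", {
  cfg <- synth_config(n_bays = 2, plots_per_bay = 6, n_stages = 1,
                      plot_px = c(4, 20))
  g <- field_grid(cfg, "R41")
  path <- tempfile(fileext = ".csv")
  write_plot_grid(g, path)
  g2 <- read_plot_grid(path)
  expect_equal(as.data.frame(g), as.data.frame(g2), tolerance = 1e-12)
  bad <- g
  bad$max_x[1] <- bad$min_x[1]
  write.csv(as.data.frame(bad), path, row.names = FALSE)
  expect_error(read_plot_grid(path), "positive area")
})

test_that("ground-reference selection picks 24 plots per bay on the trial layout", {
  cfg <- synth_config(n_bays = 3, plots_per_bay = 576, n_stages = 1)
  grids <- do.call(rbind, lapply(1:3, function(b) as.data.frame(field_grid(cfg, b))))
  class(grids) <- c("plot_grid", "data.frame")
  ref <- ground_reference_plots(grids)
  expect_equal(nrow(ref), 72)
  expect_equal(as.integer(table(ref$bay)), rep(24L, 3))
  # 12 consecutive plots behind each of 2 lines per bay
  one <- ref[ref$bay == "R40", ]
  expect_equal(length(unique(one$range)), 2)
  expect_equal(as.integer(table(one$range)), rep(12L, 2))
})

test_that("bind and subset keep samples aligned with their metadata", {
  sc <- make_test_scene()
  s <- sample_plots(sc)
  both <- bind_samples(s, s)
  expect_equal(length(both), 2 * length(s))
  sub <- both[c(2, 5)]
  expect_equal(sub$x[, 1], both$x[, 2])
  expect_equal(sub$meta$plot_id, both$meta$plot_id[c(2, 5)])
})
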