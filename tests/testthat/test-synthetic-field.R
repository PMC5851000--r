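small_cfg <- function(...) {
  synth_config(n_bays = 2, plots_per_bay = 4, n_stages = 3,
               plot_px = c(6, 30), seed = 21, ...)
}

test_that("zero cover and zero noise give pure soil plots", {
  cfg <- small_cfg(noise_sd = 0, cover_curve = c(0, 0.5, 1),
                   senescence_curve = c(0, 0, 0))
  sc <- generate_field(cfg, "R40", 1)
  g <- sc$grid
  gt <- sc$geotransform
  for (k in seq_len(nrow(g))) {
    px0 <- floor(world_to_pixel(c(g$min_x[k], g$min_y[k]), gt))
    for (b in names(sc$bands)) {
      crop <- sc$bands[[b]][px0[2] + 1:6, px0[1] + 1:30]
      expect_true(all(crop == cfg$spectra$soil[[b]]), info = b)
    }
  }
})

test_that("scenes are bit-identical for equal (seed, bay, stage) and differ across seeds", {
  cfg <- small_cfg()
  a <- generate_field(cfg, "R41", 2)
  b <- generate_field(cfg, "R41", 2)
  expect_identical(a$bands, b$bands)
  cfg2 <- small_cfg()
  cfg2$seed <- 22L
  c2 <- generate_field(cfg2, "R41", 2)
  expect_false(identical(a$bands, c2$bands))
  d <- generate_field(cfg, "R41", 3)
  expect_false(identical(a$bands, d$bands))
})

test_that("full healthy canopy reproduces the closed-form NDVI", {
  cfg <- small_cfg(noise_sd = 0, cover_curve = c(0, 0.5, 1),
                   senescence_curve = c(0, 0, 0))
  sc <- generate_field(cfg, "R40", 3)   # cover 1, senescence 0
  s <- sample_plots(sc)
  # veg spectrum has NIR 0.50, red 0.05 -> NDVI = 0.45/0.55
  expect_equal(s$meta$target_vi, rep(0.45 / 0.55, 4), tolerance = 1e-12)
})

test_that("noise-free plot means equal the realized mixture value", {
  cfg <- small_cfg(noise_sd = 0)
  ndvi_of <- function(sp) unname((sp["nir"] - sp["red"]) / (sp["nir"] + sp["red"]))
  for (stage in 1:3) {
    sc <- generate_field(cfg, "R41", stage)
    s <- sample_plots(sc)
    expected <- sc$truth$f_veg * ndvi_of(cfg$spectra$veg) +
      sc$truth$f_sen * ndvi_of(cfg$spectra$sen) +
      sc$truth$f_soil * ndvi_of(cfg$spectra$soil)
    expect_equal(s$meta$target_vi, expected, tolerance = 1e-6)
  }
})

test_that("raising senescence lowers the mean NDVI", {
  mk <- function(sen) synth_config(n_bays = 1, plots_per_bay = 4, n_stages = 1,
                                   plot_px = c(10, 60), noise_sd = 0,
                                   cover_curve = 0.9, senescence_curve = sen,
                                   sen_jitter = 0, cover_jitter = 0, seed = 5)
  mean_vi <- function(sen) {
    s <- sample_plots(generate_field(mk(sen), 1, 1))
    mean(s$meta$target_vi)
  }
  vals <- vapply(c(0, 0.3, 0.6, 0.9), mean_vi, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("per-plot deviations persist across stages within a bay", {
  cfg <- small_cfg(noise_sd = 0, cover_curve = c(0.5, 0.5, 0.5),
                   senescence_curve = c(0, 0, 0))
  s1 <- generate_field(cfg, "R40", 1)$truth$cover
  s2 <- generate_field(cfg, "R40", 2)$truth$cover
  expect_equal(s1, s2)  # same stage-curve value, same persistent effects
  other_bay <- generate_field(cfg, "R41", 1)$truth$cover
  expect_false(identical(s1, other_bay))
})

test_that("digital-number encoding matches round(reflectance * dn_max * gain)", {
  cfg <- small_cfg(noise_sd = 0)
  sc <- generate_field(cfg, "R40", 2)
  dn <- encode_dn(sc, cfg, gain = 1)
  expect_equal(dn$dn$nir[1, 1], round(sc$bands$nir[1, 1] * 65535))
  # reflectance 0.5 with gain 1 encodes to 32768; reflectance 0 to 0
  sc$bands$nir[1, 1] <- 0.5
  sc$bands$nir[1, 2] <- 0
  dn <- encode_dn(sc, cfg, gain = 1)
  expect_identical(dn$dn$nir[1, 1], 32768L)
  expect_identical(dn$dn$nir[1, 2], 0L)
  expect_error(encode_dn(sc, cfg, gain = 0.2), "gain")
})

test_that("encode followed by radiometric_scale recovers reflectance within 1/dn_max", {
  cfg <- small_cfg(noise_sd = 0.01)
  sc <- generate_field(cfg, "R41", 2)
  dn <- encode_dn(sc, cfg)
  back <- radiometric_scale(dn)
  for (b in names(sc$bands))
    expect_lt(max(abs(back$bands[[b]] - sc$bands[[b]])), 1 / cfg$dn_max)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(cover_curve = c(0.1, 0.2)), "length")
  expect_error(synth_config(cover_curve = rep(1.5, 7)), "\\[0, 1\\]")
  bad <- vi_spectra()
  bad$veg["nir"] <- 0.01
  expect_error(synth_config(spectra = bad), "NIR > red")
  cfg <- small_cfg()
  expect_error(generate_field(cfg, "R40", 9), "invalid stage")
  expect_error(generate_field(cfg, "R99", 1), "unknown bay")
})

test_that("scenes survive a TIFF round trip", {
  cfg <- small_cfg(noise_sd = 0.01)
  sc <- generate_field(cfg, "R40", 2)
  path <- file.path(tempdir(), "scene.tif")
  write_scene(sc, path)
  sc2 <- read_scene(path)
  expect_equal(names(sc2$bands), names(sc$bands))
  for (b in names(sc$bands))
    expect_equal(sc2$bands[[b]], sc$bands[[b]], tolerance = 1e-6)
  expect_equal(sc2$bay_id, "R40")
  expect_equal(sc2$stage, 2)
  expect_equal(sc2$geotransform, sc$geotransform, tolerance = 1e-12)
  expect_equal(as.data.frame(sc2$grid), as.data.frame(sc$grid),
               tolerance = 1e-9)
  unlink(c(path, sub("\\.tif$", ".yaml", path), sub("\\.tif$", "_grid.csv", path)))
})

test_that("the ablation spectra preset is iso-luminant with metameric senescence", {
  sp <- vi_spectra("ablation")
  luma <- function(s) 0.299 * s[["red"]] + 0.587 * s[["green"]] + 0.114 * s[["blue"]]
  expect_equal(luma(sp$veg), luma(sp$soil), tolerance = 1e-3)
  expect_equal(luma(sp$sen), luma(sp$soil), tolerance = 1e-3)
  # senescent visible spectrum sits on the soil-vegetation line in RGB space
  t <- (sp$sen[["red"]] - sp$soil[["red"]]) / (sp$veg[["red"]] - sp$soil[["red"]])
  for (b in c("blue", "green"))
    expect_equal(sp$sen[[b]], sp$soil[[b]] + t * (sp$veg[[b]] - sp$soil[[b]]),
                 tolerance = 1e-3)
  # but its NIR breaks the metamerism
  expect_gt(abs(sp$sen[["nir"]] - (sp$soil[["nir"]] +
                                   t * (sp$veg[["nir"]] - sp$soil[["nir"]]))),
            0.1)
})
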