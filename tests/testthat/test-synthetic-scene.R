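test_that("degenerate variogram gives a constant field; seeds reproduce", {
  cfg <- scene_config(rows = 16, cols = 16,
                      truth_variogram = variogram_model("spherical", 0,
                                                        1e-12, 10),
                      lai_sd = 0, lai_mean = 2.6, seed = 3)
  f <- generate_gaussian_field(cfg)
  expect_true(all(f == 2.6))

  cfg2 <- scene_config(rows = 32, cols = 32, seed = 11)
  expect_identical(generate_gaussian_field(cfg2),
                   generate_gaussian_field(cfg2))
  s1 <- generate_scene(scene_config(rows = 24, cols = 24, plot_count = 10,
                                    seed = 5))
  s2 <- generate_scene(scene_config(rows = 24, cols = 24, plot_count = 10,
                                    seed = 5))
  expect_identical(s1, s2)
})

test_that("invalid scene configs are rejected", {
  expect_error(scene_config(rows = 8), "rows")
  expect_error(scene_config(pixel_size = -1), "pixel_size")
  expect_error(variogram_model("spherical", 0.1, 0.9, -5), "range")
})

test_that("generated field matches its variogram model (15% pointwise)", {
  cfg <- scene_config(rows = 128, cols = 128, pixel_size = 1,
                      lai_mean = 10, lai_sd = 1,
                      truth_variogram = variogram_model("spherical", 0, 1,
                                                        20),
                      seed = 7)
  f <- generate_gaussian_field(cfg)
  idx <- with_seed(7, sample(length(f), 2000))
  rc <- arrayInd(idx, dim(f))
  pts <- point_samples(rc[, 2] - 0.5, rc[, 1] - 0.5, f[idx])
  emp <- empirical_variogram(pts, 2, 20)
  model <- cfg$truth_variogram
  ok <- is.finite(emp$gamma) & emp$lag <= 20 & emp$lag >= 2
  pred <- variogram_model_value(model, emp$lag[ok])
  expect_true(all(abs(emp$gamma[ok] - pred) / pred <= 0.15))
})

test_that("sensor rendering is physical, saturating and LAI-coupled", {
  cfg <- scene_config(rows = 24, cols = 24, noise = list(
    optical = 0, sar = 0, lidar = 0, plot_lai = 0, canopy = 0), seed = 2)
  bare <- render_sensors(matrix(0, 24, 24), matrix(1000, 24, 24), cfg)
  ndvi0 <- (bare$optical_bands$B8 - bare$optical_bands$B4) /
    (bare$optical_bands$B8 + bare$optical_bands$B4)
  expect_true(all(ndvi0 <= 0.1)) # bare soil

  sc <- tiny_scene()
  for (b in sc$optical_bands) expect_true(all(b >= 0 & b <= 1))

  cfg0 <- scene_config(rows = 48, cols = 48, noise = list(
    optical = 0, sar = 0, lidar = 0, plot_lai = 0, canopy = 0), seed = 42)
  lai <- generate_gaussian_field(cfg0)
  terr <- matrix(1000, 48, 48)
  sens <- render_sensors(lai, terr, cfg0)
  ndvi <- (sens$optical_bands$B8 - sens$optical_bands$B4) /
    (sens$optical_bands$B8 + sens$optical_bands$B4)
  expect_gte(cor(as.vector(ndvi), as.vector(lai)), 0.9)

  # saturating response: equal LAI steps give shrinking NDVI steps
  ndvi_at <- function(l) {
    s <- render_sensors(matrix(l, 2, 2), matrix(0, 2, 2), cfg0)
    ((s$optical_bands$B8 - s$optical_bands$B4) /
       (s$optical_bands$B8 + s$optical_bands$B4))[1, 1]
  }
  expect_lt(ndvi_at(6) - ndvi_at(3), ndvi_at(3) - ndvi_at(0))
  # monotone canopy height in LAI
  expect_gt(ndvi_at(3), ndvi_at(0))
})

test_that("footprints sit on tracks with the expected count and values", {
  cfg <- scene_config(rows = 48, cols = 48, pixel_size = 15,
                      track_spacing = 180, along_track_step = 100,
                      noise = list(lidar = 0), seed = 42)
  sc <- generate_scene(cfg, photons = FALSE)
  fp <- sample_footprints(sc, cfg)
  # zero sensor noise: terrain reproduced exactly at footprint pixels
  px <- laiscape:::point_to_pixel(fp$x_m, fp$y_m, 15, 48, 48)
  expect_equal(fp$h_te_best_fit, sc$terrain[cbind(px$row, px$col)])
  # count: tracks * (track length / step) within 10%
  n_tracks <- length(unique(fp$x_m))
  expected <- n_tracks * (48 * 15) / 100
  expect_lt(abs(nrow(fp) - expected) / expected, 0.1)
  # spacing error
  expect_error(sample_footprints(sc, scene_config(rows = 48, cols = 48,
                                                  track_spacing = 1e6)),
               "track_spacing")
})

test_that("plots: count, unique coordinates, noiseless recovery", {
  sc <- tiny_scene()
  plots <- sc$plots
  expect_equal(nrow(plots), 20)
  expect_false(any(duplicated(plots[, c("x_m", "y_m")])))

  cfg0 <- scene_config(rows = 48, cols = 48, plot_count = 51,
                       noise = list(plot_lai = 0), lai_sd = 0,
                       lai_mean = 3.3, seed = 9)
  sc0 <- generate_scene(cfg0, photons = FALSE)
  expect_equal(nrow(sc0$plots), 51)
  expect_true(all(abs(sc0$plots$lai - 3.3) < 1e-9))

  # measured-noise calibration: sd(plot - truth mean) ~ configured sd
  errs <- vapply(1:40, function(s) {
    cfg <- scene_config(rows = 32, cols = 32, plot_count = 51,
                        noise = list(plot_lai = 0.1), seed = s)
    sc <- generate_scene(cfg, photons = FALSE)
    truth <- vapply(seq_len(51), function(i)
      laiscape:::plot_mean_lai(sc$lai_truth, sc$plots$x_m[i],
                               sc$plots$y_m[i], 8.5, 15), 0)
    sd(sc$plots$lai - truth)
  }, 0)
  expect_gt(mean(errs), 0.07)
  expect_lt(mean(errs), 0.13)
})

test_that("coordinate conventions agree between plots, pixels and grids", {
  sc <- tiny_scene()
  px <- laiscape:::point_to_pixel(sc$plots$x_m, sc$plots$y_m, 15, 48, 48)
  expect_true(all(px$inside))
  v1 <- sc$lai_truth[cbind(px$row, px$col)]
  # the value extracted at a plot center equals the owning-pixel value
  ft <- extract_at_points(raster_stack(list(lai_grid = sc$lai_truth), 15),
                          points = sc$plots, pixel_size = 15)
  expect_equal(ft$lai_grid, v1)
})

test_that("scene round-trips through plain-text files", {
  sc <- tiny_scene()
  d <- withr::local_tempdir()
  write_scene(sc, d)
  back <- read_ascii_grid(file.path(d, "lai_truth.asc"))
  expect_equal(back$matrix, sc$lai_truth, tolerance = 1e-6)
  expect_equal(back$pixel_size, 15)
  fp <- read.csv(file.path(d, "footprints.csv"))
  expect_named(fp, c("x_m", "y_m", "h_te_best_fit", "h_te_interp",
                     "h_mean_canopy_abs", "solar_elevation"))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 42)
})
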