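test_that("resampling: median composite, constants, area match", {
  cst <- raster_stack(list(a = matrix(3.7, 30, 30)), pixel_size = 10)
  out <- resample_to_grid(cst, 15)
  expect_true(all(abs(out$bands$a - 3.7) < 1e-12))
  expect_equal(out$pixel_size, 15)

  # temporal median is outlier-robust: {1, 2, 100} -> 2
  tseq <- lapply(c(1, 2, 100), function(v)
    raster_stack(list(a = matrix(v, 20, 20)), 10))
  med <- resample_to_grid(tseq, 10)
  expect_true(all(abs(med$bands$a - 2) < 1e-12))

  # smooth field is interpolated, not shifted: error stays small
  f <- outer(seq_len(40), seq_len(40), function(i, j)
    sin(i / 8) + cos(j / 10))
  rs <- resample_to_grid(raster_stack(list(f = f), 10), 15)
  tgt <- outer(seq_len(nrow(rs$bands$f)), seq_len(ncol(rs$bands$f)),
               function(i, j) sin(((i - 0.5) * 1.5 + 0.5) / 8) +
                 cos(((j - 0.5) * 1.5 + 0.5) / 10))
  expect_lt(max(abs(rs$bands$f - tgt)), 0.02)

  expect_error(resample_to_grid(cst, 1e5), "coarser")
})

test_that("GLCM features match the exhaustive enumeration oracle", {
  # fixed toy matrix, orientation 0, symmetric
  toy <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 0, 2, 2, 2, 2, 2, 3, 3),
                4, 4, byrow = TRUE)
  tx <- glcm_textures(toy / 3, glcm_spec(window = 3, levels = 4,
                                         orientations = 0))
  q <- laiscape:::quantize_band(toy / 3, 4)
  feats <- c("Mean", "Variance", "Homogeneity", "Contrast",
             "Dissimilarity", "Entropy", "SecondMoment", "Correlation")
  for (ctr in list(c(2, 2), c(3, 3), c(1, 4))) {
    o <- glcm_oracle(q, 4, 3, 0, TRUE, ctr)
    expect_equal(o$Psum, 1, tolerance = 1e-12)
    for (f in feats) {
      expect_equal(tx[[f]][ctr[1], ctr[2]], o[[f]], tolerance = 1e-12,
                   label = sprintf("%s at (%d,%d)", f, ctr[1], ctr[2]))
    }
  }

  # 10 random 6x6 matrices, all four orientations
  for (s in 1:10) {
    b <- with_seed(s, matrix(runif(36), 6, 6))
    spec <- glcm_spec(window = 5, levels = 8)
    tx <- glcm_textures(b, spec)
    q <- laiscape:::quantize_band(b, 8)
    ctr <- c(3, 4)
    o <- glcm_oracle(q, 8, 5, c(0, 45, 90, 135), TRUE, ctr)
    for (f in feats) {
      expect_equal(tx[[f]][ctr[1], ctr[2]], o[[f]], tolerance = 1e-12,
                   label = sprintf("seed %d %s", s, f))
    }
  }
})

test_that("GLCM closed forms: constant window and checkerboard", {
  cw <- glcm_textures(matrix(1, 6, 6), glcm_spec(window = 3, levels = 16))
  expect_true(all(cw$Contrast == 0) && all(cw$Dissimilarity == 0))
  expect_true(all(cw$Homogeneity == 1) && all(cw$SecondMoment == 1))
  expect_true(all(cw$Entropy == 0))
  expect_true(all(cw$Correlation == 0) && all(cw$flat_flag))

  L <- 16
  cb <- outer(1:7, 1:7, function(i, j) (i + j) %% 2)
  tx <- glcm_textures(cb, glcm_spec(window = 5, levels = L,
                                    orientations = 0))
  expect_equal(tx$Contrast[4, 4], (L - 1)^2)
  expect_equal(tx$Homogeneity[4, 4], 1 / (1 + (L - 1)^2))
})

test_that("vegetation indices follow the tabulated formulas", {
  mk <- function(v) matrix(v, 2, 2)
  st <- raster_stack(list(B2 = mk(0.05), B3 = mk(0.1), B4 = mk(0.1),
                          B8 = mk(0.5)), 15)
  idx <- vegetation_indices(st)
  expect_equal(idx$NDVI[1, 1], 0.4 / 0.6, tolerance = 1e-4)
  expect_equal(idx$EVI[1, 1], 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1),
               tolerance = 1e-4)
  expect_equal(idx$MSAVI[1, 1], (2 - sqrt(4 - 3.2)) / 2, tolerance = 1e-4)
  expect_equal(idx$EVI2[1, 1], 2.5 * 0.4 / 1.6)
  expect_equal(idx$SAVI[1, 1], 0.4 * 1.5 / 1.1)
  expect_equal(idx$OSAVI[1, 1], 0.4 / 0.76)
  expect_equal(idx$GRVI[1, 1], 1)

  # B8 = B4: zero-difference indices
  eq <- raster_stack(list(B2 = mk(0.05), B3 = mk(0.1), B4 = mk(0.3),
                          B8 = mk(0.3)), 15)
  ieq <- vegetation_indices(eq)
  expect_true(all(ieq$NDVI == 0) && all(ieq$DVI == 0) &&
                all(ieq$RVI == 1))

  # duplicated formulas as printed; conventional RDVI behind the flag
  sc <- tiny_scene()
  stack <- raster_stack(sc$optical_bands, 15)
  v <- vegetation_indices(stack)
  expect_identical(v$RDVI, v$NDVI)
  expect_identical(v$IDVI, v$GNDVI)
  v2 <- vegetation_indices(stack, rdvi_conventional = TRUE)
  expect_false(identical(v2$RDVI, v2$NDVI))

  # bounds on positive reflectances
  expect_true(all(abs(v$NDVI) <= 1, na.rm = TRUE))
  expect_true(all(abs(v$GNDVI) <= 1, na.rm = TRUE))
  expect_true(all(v$RVI > 0, na.rm = TRUE))

  expect_error(vegetation_indices(raster_stack(list(B2 = mk(1)), 15)),
               "missing band")
})

test_that("point extraction samples the owning pixel and drops bad rows", {
  g <- matrix(seq_len(16), 4, 4)
  st <- raster_stack(list(v = g), pixel_size = 10)
  pts <- data.frame(x_m = c(15, 35, 95), y_m = c(15, 5, 5),
                    lai = c(1, 2, 3))
  expect_message(
    ft <- extract_at_points(st, points = pts, pixel_size = 10),
    "outside")
  expect_equal(nrow(ft), 2)
  expect_equal(ft$v, c(g[2, 2], g[1, 4]))

  # point exactly at a pixel center
  ctr <- data.frame(x_m = 25, y_m = 35, lai = 1)
  expect_equal(extract_at_points(st, points = ctr, pixel_size = 10)$v,
               g[4, 3])

  expect_error(extract_at_points(st, points = data.frame(
    x_m = 500, y_m = 500, lai = 1), pixel_size = 10), "all rows dropped")
})

test_that("the default scene layout yields 42 predictors + response", {
  sc <- tiny_scene()
  surfaces <- list(
    h_te_best_fit = sc$terrain, h_te_interp = sc$terrain,
    h_mean_canopy_abs = sc$canopy_height, solar_elevation = sc$solar_field)
  ft <- scene_feature_table(sc, surfaces)
  expect_s3_class(ft, "feature_table")
  expect_equal(ncol(ft), 43) # lai + 4 atlas + 2 SAR + 16 textures + 8 + 12
  expect_equal(nrow(ft), nrow(sc$plots))
  expect_true(all(c("VV_Mean", "VV_Dissimilarity", "VH_Homogeneity",
                    "NDVI", "EVI2", "h_te_best_fit") %in% names(ft)))
  expect_false(any(is.na(ft)))
})
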