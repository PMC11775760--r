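#' Synthetic-scene configuration
#'
#' Describes the toy landscape every downstream stage is exercised on: a
#' spatially autocorrelated LAI field with a known variogram, terrain,
#' sensor renderings, quasi-regular altimeter tracks and circular field
#' plots.  Defaults follow the emulated campaign: 15 m pixels, 51 circular
#' plots of 8.5 m radius, 100 m along-track footprint segments.
#'
#' @param rows,cols grid size in pixels (>= 16).
#' @param pixel_size pixel edge, metres.
#' @param lai_mean,lai_sd first two moments of the LAI field (unitless).
#' @param truth_variogram [variogram_model] of the latent Gaussian LAI field
#'   (range in metres; the sill is rescaled to `lai_sd^2`).
#' @param terrain_relief peak-to-peak terrain amplitude, metres.
#' @param plot_count number of field plots.
#' @param plot_radius plot radius, metres.
#' @param track_spacing distance between parallel ground tracks, metres.
#' @param along_track_step footprint segment length, metres.
#' @param noise list of per-sensor noise levels: `optical` (reflectance sd),
#'   `sar` (dB sd), `lidar` (m sd on terrain/canopy attributes),
#'   `plot_lai` (sd on measured plot LAI), `canopy` (m sd on the canopy
#'   height grid).
#' @param seed integer; fixed seed implies a bit-identical scene.
#' @return a `scene_config` object.
#' @export
scene_config <- function(rows = 120, cols = 120, pixel_size = 15,
                         lai_mean = 2.6, lai_sd = 0.8,
                         truth_variogram = variogram_model(
                           "spherical", nugget = 0.05, psill = 0.95,
                           range_a = 450),
                         terrain_relief = 120, plot_count = 51,
                         plot_radius = 8.5, track_spacing = 300,
                         along_track_step = 100,
                         noise = list(optical = 0.01, sar = 0.5,
                                      lidar = 0.3, plot_lai = 0.15,
                                      canopy = 0.5),
                         seed = 1) {
  if (rows < 16 || cols < 16) stopf("rows and cols must be >= 16")
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  if (lai_sd < 0) stopf("lai_sd must be >= 0")
  if (!inherits(truth_variogram, "variogram_model")) {
    stopf("truth_variogram must be a variogram_model")
  }
  defaults <- list(optical = 0.01, sar = 0.5, lidar = 0.3, plot_lai = 0.15,
                   canopy = 0.5)
  noise <- utils::modifyList(defaults, noise)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size = pixel_size, lai_mean = lai_mean,
                 lai_sd = lai_sd, truth_variogram = truth_variogram,
                 terrain_relief = terrain_relief,
                 plot_count = as.integer(plot_count),
                 plot_radius = plot_radius, track_spacing = track_spacing,
                 along_track_step = along_track_step, noise = noise,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Unconditional stationary Gaussian field by circulant embedding: the
# covariance of the torus-wrapped grid is diagonalized by the 2-D FFT, so a
# field with exactly the requested covariance (up to clipped negative
# embedding eigenvalues, which are negligible at 2x padding for the models
# used here) is one FFT of white complex noise away.
gaussian_field_unit <- function(rows, cols, pixel_size, model) {
  p1 <- 2^ceiling(log2(2 * rows))
  p2 <- 2^ceiling(log2(2 * cols))
  # structural (nugget-free) covariance of torus distances
  r <- c(0:(p1 %/% 2), (p1 %/% 2 - 1):1)[1:p1]
  s <- c(0:(p2 %/% 2), (p2 %/% 2 - 1):1)[1:p2]
  hd <- outer(r^2, s^2, `+`)
  h <- sqrt(hd) * pixel_size
  struct_model <- variogram_model(model$kind, 0, 1, model$range_a)
  cov_base <- 1 - variogram_model_value(struct_model, h)
  lambda <- Re(fft(cov_base))
  lambda[lambda < 0] <- 0
  z <- matrix(complex(real = rnorm(p1 * p2), imaginary = rnorm(p1 * p2)),
              p1, p2)
  f <- fft(sqrt(lambda) * z) / sqrt(p1 * p2)
  Re(f)[1:rows, 1:cols]
}

#' Generate the latent LAI truth field
#'
#' An unconditional Gaussian random field with the configured variogram
#' (nugget rendered as white noise on top of the structured component),
#' rescaled to `lai_mean` / `lai_sd` and truncated at 0 so LAI stays
#' physical.
#'
#' @param config a [scene_config].
#' @return `rows x cols` matrix of LAI.
#' @export
generate_gaussian_field <- function(config) {
  vm <- config$truth_variogram
  if (!(vm$sill >= 0)) stopf("invalid variogram")
  if (vm$sill == 0 || config$lai_sd == 0) {
    return(matrix(config$lai_mean, config$rows, config$cols))
  }
  with_seed(derive_seed(config$seed, 1L), {
    f <- gaussian_field_unit(config$rows, config$cols, config$pixel_size, vm)
    if (vm$nugget > 0) {
      w <- sqrt(vm$nugget / vm$sill)
      f <- f * sqrt(vm$psill / vm$sill) +
        matrix(rnorm(config$rows * config$cols), config$rows,
               config$cols) * w
    }
    pmax(config$lai_mean + f * config$lai_sd, 0)
  })
}

# smooth auxiliary fields (terrain, solar elevation) use a long-range
# Gaussian structure covering ~half the scene extent
smooth_field <- function(rows, cols, pixel_size, frac = 0.5) {
  extent <- max(rows, cols) * pixel_size
  m <- variogram_model("gaussian", 0, 1, frac * extent)
  gaussian_field_unit(rows, cols, pixel_size, m)
}

.soil_refl <- c(B2 = 0.10, B3 = 0.14, B4 = 0.18, B5 = 0.19, B6 = 0.20,
                B7 = 0.20, B8 = 0.21, B8A = 0.21)
.leaf_refl <- c(B2 = 0.03, B3 = 0.06, B4 = 0.04, B5 = 0.15, B6 = 0.30,
                B7 = 0.40, B8 = 0.45, B8A = 0.47)
.canopy_hmax <- 28   # m, tall-bamboo stand ceiling
.canopy_k <- 0.5     # saturation rate shared with the optical mixing model

#' Render optical bands, SAR backscatter and canopy height from LAI truth
#'
#' Optical forward model: linear mixing of soil and leaf endmember
#' reflectances with vegetated fraction `1 - exp(-k LAI)`, `k = 0.5`, which
#' yields the saturating index-LAI response optical sensors show over dense
#' canopies.  Canopy height is a monotone saturating function of LAI; VV/VH
#' backscatter (dB) are affine in canopy height with speckle-like Gaussian
#' noise.
#'
#' @param lai_truth LAI matrix.
#' @param terrain elevation matrix (same geometry).
#' @param config a [scene_config].
#' @return list with `optical_bands` (named list of reflectance matrices in
#'   `[0, 1]`), `sar_bands` (named list, dB) and `canopy_height` (m).
#' @export
render_sensors <- function(lai_truth, terrain, config) {
  if (!all(dim(lai_truth) == dim(terrain))) {
    stopf("lai_truth and terrain must share geometry")
  }
  with_seed(derive_seed(config$seed, 2L), {
    nr <- nrow(lai_truth); nc <- ncol(lai_truth)
    fc <- 1 - exp(-.canopy_k * lai_truth)
    optical <- lapply(names(.soil_refl), function(b) {
      refl <- .leaf_refl[[b]] * fc + .soil_refl[[b]] * (1 - fc)
      if (config$noise$optical > 0) {
        refl <- refl + matrix(rnorm(nr * nc, sd = config$noise$optical),
                              nr, nc)
      }
      pmin(pmax(refl, 0), 1)
    })
    names(optical) <- names(.soil_refl)
    canopy <- .canopy_hmax * lai_truth / (lai_truth + 2)
    if (config$noise$canopy > 0) {
      canopy <- pmax(canopy +
                       matrix(rnorm(nr * nc, sd = config$noise$canopy),
                              nr, nc), 0)
    }
    sar <- list(
      VV = -18 + 0.40 * canopy,
      VH = -24 + 0.50 * canopy
    )
    if (config$noise$sar > 0) {
      sar <- lapply(sar, function(s)
        s + matrix(rnorm(nr * nc, sd = config$noise$sar), nr, nc))
    }
    list(optical_bands = optical, sar_bands = sar, canopy_height = canopy)
  })
}

#' Sample altimeter footprints along quasi-regular ground tracks
#'
#' Tracks run north-south at `track_spacing` intervals; footprint segments
#' sit every `along_track_step` metres.  Terrain attributes
#' (`h_te_best_fit`, `h_te_interp`) are the terrain grid value plus small
#' independent LiDAR noises, `h_mean_canopy_abs` the canopy height plus
#' noise, and `solar_elevation` a smooth low-frequency field.
#'
#' @param scene a `synthetic_scene` (or list with `terrain`,
#'   `canopy_height`, `solar_field`).
#' @param config a [scene_config].
#' @return a `footprint_table` data frame with `x_m`, `y_m` and the four
#'   attribute columns.
#' @export
sample_footprints <- function(scene, config) {
  width <- config$cols * config$pixel_size
  height <- config$rows * config$pixel_size
  if (config$track_spacing / 2 >= width) {
    stopf("track_spacing (%g m) exceeds the scene width (%g m)",
          config$track_spacing, width)
  }
  track_x <- seq(config$track_spacing / 2, width - config$pixel_size / 100,
                 by = config$track_spacing)
  along_y <- seq(config$along_track_step / 2,
                 height - config$pixel_size / 100,
                 by = config$along_track_step)
  pts <- expand.grid(y_m = along_y, x_m = track_x)
  px <- point_to_pixel(pts$x_m, pts$y_m, config$pixel_size,
                       config$rows, config$cols)
  pts <- pts[px$inside, ]
  px <- px[px$inside, ]
  with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(pts)
    terr <- scene$terrain[cbind(px$row, px$col)]
    can <- scene$canopy_height[cbind(px$row, px$col)]
    sol <- scene$solar_field[cbind(px$row, px$col)]
    sdn <- config$noise$lidar
    out <- data.frame(
      x_m = pts$x_m, y_m = pts$y_m,
      h_te_best_fit = terr + rnorm(n, sd = sdn),
      h_te_interp = terr + rnorm(n, sd = sdn),
      h_mean_canopy_abs = pmax(can + rnorm(n, sd = sdn), 0),
      solar_elevation = sol
    )
    class(out) <- c("footprint_table", "data.frame")
    out
  })
}

#' Sample circular field plots
#'
#' Plot centers are spread by sequential rejection sampling under a
#' minimum-distance rule; plot LAI is the mean of the truth field within
#' the plot radius plus Gaussian measurement noise.
#'
#' @param scene a `synthetic_scene` (needs `lai_truth`).
#' @param config a [scene_config].
#' @return a `plot_table` data frame with `plot_id`, `x_m`, `y_m`, `lai`.
#' @export
sample_plots <- function(scene, config) {
  if (config$plot_count < 2) stopf("plot_count must be >= 2")
  width <- config$cols * config$pixel_size
  height <- config$rows * config$pixel_size
  if (2 * config$plot_radius >= min(width, height)) {
    stopf("plot_radius too large for the scene extent")
  }
  min_dist <- 0.5 * sqrt(width * height / config$plot_count)
  with_seed(derive_seed(config$seed, 4L), {
    xs <- ys <- numeric(0)
    tries <- 0
    while (length(xs) < config$plot_count && tries < 20000) {
      tries <- tries + 1
      cx <- runif(1, config$plot_radius, width - config$plot_radius)
      cy <- runif(1, config$plot_radius, height - config$plot_radius)
      if (!length(xs) || all((xs - cx)^2 + (ys - cy)^2 >= min_dist^2)) {
        xs <- c(xs, cx)
        ys <- c(ys, cy)
      }
    }
    if (length(xs) < config$plot_count) {
      stopf("could not place %d plots with min distance %g m",
            config$plot_count, min_dist)
    }
    lai <- vapply(seq_along(xs), function(i) {
      plot_mean_lai(scene$lai_truth, xs[i], ys[i], config$plot_radius,
                    config$pixel_size)
    }, 0)
    if (config$noise$plot_lai > 0) {
      lai <- lai + rnorm(length(lai), sd = config$noise$plot_lai)
    }
    out <- data.frame(plot_id = seq_along(xs), x_m = xs, y_m = ys,
                      lai = pmax(lai, 1e-6))
    class(out) <- c("plot_table", "data.frame")
    out
  })
}

# mean of grid pixels whose centers fall within `radius` of (cx, cy);
# falls back to the owning pixel when the radius is sub-pixel
plot_mean_lai <- function(grid, cx, cy, radius, pixel_size) {
  nr <- nrow(grid); nc <- ncol(grid)
  r0 <- max(1L, floor((cy - radius) / pixel_size) + 1L)
  r1 <- min(nr, floor((cy + radius) / pixel_size) + 1L)
  c0 <- max(1L, floor((cx - radius) / pixel_size) + 1L)
  c1 <- min(nc, floor((cx + radius) / pixel_size) + 1L)
  rows <- r0:r1; cols <- c0:c1
  ctr_y <- (rows - 0.5) * pixel_size
  ctr_x <- (cols - 0.5) * pixel_size
  d2 <- outer((ctr_y - cy)^2, (ctr_x - cx)^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) {
    px <- point_to_pixel(cx, cy, pixel_size, nr, nc)
    return(grid[px$row, px$col])
  }
  mean(grid[rows, cols][inside])
}

#' Generate a complete synthetic scene
#'
#' Assembles truth LAI, terrain, sensor renderings, footprints, plots and
#' photon transects into one reproducible object; a fixed seed yields a
#' bit-identical scene.
#'
#' @param config a [scene_config].
#' @param photons also simulate photon transects (slowest part; default
#'   TRUE).
#' @return a `synthetic_scene` list.
#' @export
generate_scene <- function(config = scene_config(), photons = TRUE) {
  lai <- generate_gaussian_field(config)
  terrain <- with_seed(derive_seed(config$seed, 5L), {
    f <- smooth_field(config$rows, config$cols, config$pixel_size, 0.5)
    rng <- range(f)
    if (diff(rng) > 0) {
      (f - rng[1]) / diff(rng) * config$terrain_relief + 1000
    } else {
      matrix(1000, config$rows, config$cols)
    }
  })
  solar <- with_seed(derive_seed(config$seed, 6L), {
    30 + 5 * smooth_field(config$rows, config$cols, config$pixel_size, 0.8)
  })
  sensors <- render_sensors(lai, terrain, config)
  scene <- list(config = config, lai_truth = lai, terrain = terrain,
                canopy_height = sensors$canopy_height,
                optical_bands = sensors$optical_bands,
                sar_bands = sensors$sar_bands, solar_field = solar)
  scene$footprints <- sample_footprints(scene, config)
  scene$plots <- sample_plots(scene, config)
  if (photons) {
    scene$photon_transects <- simulate_photon_transects(scene, config)
  }
  class(scene) <- "synthetic_scene"
  scene
}

#' Write a scene to plain-text files
#'
#' Emits one ASCII grid per band/surface, CSV footprint and plot tables
#' (columns named exactly `x_m`, `y_m`, `h_te_best_fit`, `h_te_interp`,
#' `h_mean_canopy_abs`, `solar_elevation`, `lai`) and a JSON manifest
#' echoing the seed and configuration.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- scene$config$pixel_size
  write_ascii_grid(scene$lai_truth, file.path(dir, "lai_truth.asc"), ps)
  write_ascii_grid(scene$terrain, file.path(dir, "terrain.asc"), ps)
  write_ascii_grid(scene$canopy_height, file.path(dir, "canopy_height.asc"),
                   ps)
  for (b in names(scene$optical_bands)) {
    write_ascii_grid(scene$optical_bands[[b]],
                     file.path(dir, paste0("optical_", b, ".asc")), ps)
  }
  for (b in names(scene$sar_bands)) {
    write_ascii_grid(scene$sar_bands[[b]],
                     file.path(dir, paste0("sar_", b, ".asc")), ps)
  }
  write.csv(scene$footprints, file.path(dir, "footprints.csv"),
            row.names = FALSE)
  write.csv(scene$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  cfg <- scene$config
  cfg$truth_variogram <- unclass(cfg$truth_variogram)
  jsonlite::write_json(list(seed = scene$config$seed, config = unclass(cfg)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
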