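#' Raster stack container
#'
#' A named list of equally shaped matrices sharing one geometry (top-left
#' origin, square pixels).
#'
#' @param bands named list of numeric matrices.
#' @param pixel_size pixel edge, metres.
#' @param nodata marker value treated as missing (default `NA`).
#' @return a `raster_stack`.
#' @export
raster_stack <- function(bands, pixel_size, nodata = NA_real_) {
  if (!length(bands) || is.null(names(bands)) ||
      anyDuplicated(names(bands))) {
    stopf("bands must be a non-empty uniquely named list")
  }
  d <- dim(bands[[1]])
  if (!all(vapply(bands, function(b) all(dim(b) == d), TRUE))) {
    stopf("all bands must share the same shape")
  }
  structure(list(bands = bands, pixel_size = pixel_size, nodata = nodata),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("raster_stack: %d band(s) %dx%d @ %g m\n  %s\n",
              length(x$bands), d[1], d[2], x$pixel_size,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

# Keys cubic-convolution kernel, a = -0.5
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# separable cubic-convolution resampling of one matrix to a new pixel size,
# sampling target pixel centers in the shared metric frame
resample_band_cubic <- function(m, in_ps, out_ps) {
  nr <- nrow(m); nc <- ncol(m)
  out_nr <- max(1L, floor(nr * in_ps / out_ps))
  out_nc <- max(1L, floor(nc * in_ps / out_ps))
  # fractional source coordinates (unit = source pixels, center at i - 0.5)
  src_r <- ((seq_len(out_nr) - 0.5) * out_ps) / in_ps + 0.5
  src_c <- ((seq_len(out_nc) - 0.5) * out_ps) / in_ps + 0.5
  interp_1d <- function(mat, src) {
    # interpolate along rows of mat at positions src (length L) -> L x ncol
    n <- nrow(mat)
    base <- floor(src)
    out <- matrix(0, length(src), ncol(mat))
    wsum <- numeric(length(src))
    for (k in -1:2) {
      idx <- pmin(pmax(base + k, 1L), n) # clamp = edge replication
      w <- cubic_kernel(src - (base + k))
      out <- out + mat[idx, , drop = FALSE] * w
      wsum <- wsum + w
    }
    out / wsum
  }
  tmp <- interp_1d(m, src_r)
  t(interp_1d(t(tmp), src_c))
}

#' Resample imagery to a common analysis grid
#'
#' A temporal sequence of stacks is first reduced to one composite by the
#' pixelwise median (outlier-robust), then spatially resampled by cubic
#' convolution to the target pixel size.
#'
#' @param stack a [raster_stack] or list of them (temporal sequence sharing
#'   band names and geometry).
#' @param target_pixel target pixel edge, metres (default 15).
#' @return a [raster_stack] at the target resolution.
#' @export
resample_to_grid <- function(stack, target_pixel = 15) {
  if (target_pixel <= 0) stopf("target_pixel must be positive")
  if (!inherits(stack, "raster_stack")) {
    if (!is.list(stack) || !length(stack)) stopf("invalid stack input")
    first <- stack[[1]]
    med <- lapply(names(first$bands), function(b) {
      arr <- vapply(stack, function(s) s$bands[[b]],
                    first$bands[[b]])
      apply(array(arr, c(dim(first$bands[[b]]), length(stack))),
            c(1, 2), median)
    })
    names(med) <- names(first$bands)
    stack <- raster_stack(med, first$pixel_size, first$nodata)
  }
  d <- dim(stack$bands[[1]])
  if (target_pixel >= min(d) * stack$pixel_size) {
    stopf("target pixel (%g m) is coarser than the raster extent",
          target_pixel)
  }
  out <- lapply(stack$bands, resample_band_cubic,
                in_ps = stack$pixel_size, out_ps = target_pixel)
  raster_stack(out, target_pixel, stack$nodata)
}

#' GLCM specification
#'
#' Defaults mirror common practice for SAR texture extraction: 5x5 window,
#' displacement 1, 64 gray levels, four orientations averaged, symmetric
#' counting.
#'
#' @param window odd window edge in pixels.
#' @param displacement co-occurrence offset in pixels.
#' @param levels number of gray levels (>= 2).
#' @param orientations orientation angles in degrees (subset of
#'   0/45/90/135).
#' @param symmetric count each pair in both directions.
#' @return a `glcm_spec`.
#' @export
glcm_spec <- function(window = 5, displacement = 1, levels = 64,
                      orientations = c(0, 45, 90, 135), symmetric = TRUE) {
  if (window %% 2 != 1) stopf("window must be odd")
  if (levels < 2) stopf("levels must be >= 2")
  if (!all(orientations %in% c(0, 45, 90, 135))) {
    stopf("orientations must be among 0, 45, 90, 135 degrees")
  }
  structure(list(window = as.integer(window),
                 displacement = as.integer(displacement),
                 levels = as.integer(levels),
                 orientations = orientations,
                 symmetric = isTRUE(symmetric)),
            class = "glcm_spec")
}

# orientation angle -> (drow, dcol) at displacement d; row axis points down
orientation_offsets <- function(orientations, d) {
  m <- t(vapply(orientations, function(a) {
    switch(as.character(a),
           "0" = c(0L, d),
           "45" = c(-d, d),
           "90" = c(-d, 0L),
           "135" = c(-d, -d))
  }, integer(2)))
  storage.mode(m) <- "integer"
  m
}

# global min-max quantization to 0..levels-1 (constant band -> level 0)
quantize_band <- function(band, levels) {
  rng <- range(band, finite = TRUE)
  if (!(rng[2] > rng[1])) {
    q <- matrix(0L, nrow(band), ncol(band))
  } else {
    q <- floor((band - rng[1]) / (rng[2] - rng[1]) * levels)
    q[q >= levels] <- levels - 1L
    storage.mode(q) <- "integer"
  }
  q
}

#' Sliding-window GLCM texture features
#'
#' Quantizes the band globally to `levels` gray values, accumulates
#' symmetric co-occurrence counts at the given displacement for each
#' orientation within each (reflect-padded) window, averages the
#' orientation matrices, normalizes to probabilities `F(i, j)` and
#' evaluates the eight classic statistics: Mean, Variance, Homogeneity,
#' Contrast, Dissimilarity, Entropy (natural log, `0 ln 0 = 0`), Second
#' Moment and Correlation (0 with a flag on zero-variance windows).
#'
#' @param band numeric matrix.
#' @param spec a [glcm_spec].
#' @return named list of 8 texture matrices plus `flat_flag` (logical
#'   matrix marking zero-variance windows).
#' @export
glcm_textures <- function(band, spec = glcm_spec()) {
  if (any(!is.finite(band))) stopf("band must be finite")
  if (spec$window > min(dim(band))) stopf("window larger than the grid")
  q <- quantize_band(band, spec$levels)
  off <- orientation_offsets(spec$orientations, spec$displacement)
  cpp_glcm_textures(q, spec$levels, spec$window, off, spec$symmetric)
}

#' Vegetation indices from optical bands
#'
#' Computes the 12 classic broadband indices used for LAI modeling.  Note
#' RDVI and IDVI are implemented exactly as commonly tabulated alongside
#' this index set, which makes RDVI identical to NDVI and IDVI identical to
#' GNDVI; set `rdvi_conventional = TRUE` for the square-root-denominator
#' RDVI instead.  Zero denominators yield `NA`.
#'
#' @param stack a [raster_stack] containing at least B2, B3, B4, B8.
#' @param savi_L SAVI soil-adjustment factor (default 0.5).
#' @param rdvi_conventional use `(B8-B4)/sqrt(B8+B4)` for RDVI.
#' @return named list of 12 index matrices.
#' @export
vegetation_indices <- function(stack, savi_L = 0.5,
                               rdvi_conventional = FALSE) {
  need <- c("B2", "B3", "B4", "B8")
  missing <- setdiff(need, names(stack$bands))
  if (length(missing)) {
    stopf("missing band(s): %s", paste(missing, collapse = ", "))
  }
  B2 <- stack$bands$B2; B3 <- stack$bands$B3
  B4 <- stack$bands$B4; B8 <- stack$bands$B8
  safe_div <- function(num, den) {
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  ndvi <- safe_div(B8 - B4, B8 + B4)
  gndvi <- safe_div(B8 - B3, B8 + B3)
  idx <- list(
    NDVI = ndvi,
    DVI = B8 - B4,
    SAVI = safe_div((B8 - B4) * (1 + savi_L), B8 + B4 + savi_L),
    OSAVI = safe_div(B8 - B4, B8 + B4 + 0.16),
    EVI = safe_div(2.5 * (B8 - B4), B8 + 6 * B4 - 7.5 * B2 + 1),
    EVI2 = safe_div(2.5 * (B8 - B4), B8 + B4 + 1),
    RVI = safe_div(B8, B4),
    MSAVI = (2 * B8 + 1 - sqrt(pmax((2 * B8 + 1)^2 - 8 * (B8 - B4), 0))) / 2,
    GNDVI = gndvi,
    GRVI = safe_div(B3, B4),
    RDVI = if (rdvi_conventional) {
      safe_div(B8 - B4, sqrt(pmax(B8 + B4, 0)))
    } else {
      ndvi
    },
    IDVI = gndvi
  )
  idx
}

#' Assemble a plot-level feature table
#'
#' Samples every provided layer at the pixel containing each point center
#' (layers were deliberately area-matched to the plots, so center-pixel
#' sampling, not a radius mean).  Rows containing any missing value are
#' dropped with a log message.
#'
#' @param stack a [raster_stack] of base bands (may be `NULL`).
#' @param textures named list of texture matrices (may be `NULL`); names
#'   become column names (`VV_Mean`, ...).
#' @param indices named list of index matrices (may be `NULL`).
#' @param points data frame with `x_m`, `y_m` and optionally `lai` plus
#'   footprint attribute columns to carry through.
#' @param pixel_size pixel size of all layers, metres.
#' @param carry point-table columns copied into the output (default: all
#'   except coordinates).
#' @return a `feature_table` data frame, one row per retained point.
#' @export
extract_at_points <- function(stack = NULL, textures = NULL, indices = NULL,
                              points, pixel_size,
                              carry = setdiff(names(points),
                                              c("x_m", "y_m"))) {
  layers <- list()
  if (!is.null(stack)) layers <- c(layers, stack$bands)
  if (!is.null(textures)) layers <- c(layers, textures)
  if (!is.null(indices)) layers <- c(layers, indices)
  layers <- layers[!vapply(layers, is.logical, TRUE)] # drop flag layers
  if (!length(layers)) stopf("no layers supplied")
  d <- dim(layers[[1]])
  px <- point_to_pixel(points$x_m, points$y_m, pixel_size, d[1], d[2])
  inside <- px$inside
  if (any(!inside)) {
    log_msg("extract_at_points: dropping %d point(s) outside the extent",
            sum(!inside))
  }
  vals <- lapply(layers, function(l) {
    v <- rep(NA_real_, nrow(points))
    v[inside] <- l[cbind(px$row[inside], px$col[inside])]
    v
  })
  out <- cbind(points[, intersect(carry, names(points)), drop = FALSE],
               as.data.frame(vals))
  ok <- inside & stats::complete.cases(out)
  if (any(inside & !stats::complete.cases(out))) {
    log_msg("extract_at_points: dropping %d row(s) with missing layer %s",
            sum(inside & !stats::complete.cases(out)), "values")
  }
  out <- out[ok, , drop = FALSE]
  if (!nrow(out)) stopf("all rows dropped during extraction")
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Full feature table for a synthetic scene
#'
#' Convenience wrapper producing the default 42-predictor layout: 4
#' footprint (ATLAS-style) attributes, VV/VH backscatter, 16 GLCM textures
#' (8 per SAR band), 8 optical bands and 12 vegetation indices, joined to
#' the plot table by nearest-footprint attributes and center-pixel raster
#' sampling.
#'
#' @param scene a `synthetic_scene`.
#' @param surfaces named list of footprint-attribute surfaces (matrices on
#'   the scene grid), e.g. the SGCS means for `h_te_best_fit` etc.
#' @param glcm a [glcm_spec].
#' @return a `feature_table` with `lai` response and 42 predictors.
#' @export
scene_feature_table <- function(scene, surfaces, glcm = glcm_spec()) {
  cfg <- scene$config
  textures <- list()
  for (b in names(scene$sar_bands)) {
    tx <- glcm_textures(scene$sar_bands[[b]], glcm)
    tx$flat_flag <- NULL
    names(tx) <- paste(b, names(tx), sep = "_")
    textures <- c(textures, tx)
  }
  opt <- raster_stack(scene$optical_bands, cfg$pixel_size)
  idx <- vegetation_indices(opt)
  base <- raster_stack(c(scene$optical_bands, scene$sar_bands),
                       cfg$pixel_size)
  atlas <- lapply(surfaces, identity)
  extract_at_points(base, c(atlas, textures), idx, scene$plots,
                    cfg$pixel_size, carry = "lai")
}
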