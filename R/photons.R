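#' Photon cloud container
#'
#' @param along_track along-track coordinate, metres (sorted on
#'   construction).
#' @param elevation photon elevation, metres.
#' @param true_label optional construction labels
#'   (`ground`/`canopy`/`noise`), available for synthetic clouds only.
#' @return a `photon_cloud` data frame with `pred_label` initialized to
#'   `"unclassified"`.
#' @export
photon_cloud <- function(along_track, elevation, true_label = NULL) {
  n <- length(along_track)
  if (length(elevation) != n) stopf("coordinate length mismatch")
  if (is.null(true_label)) true_label <- rep(NA_character_, n)
  lv <- c("ground", "canopy", "noise")
  if (!all(is.na(true_label) | true_label %in% lv)) {
    stopf("true_label must be one of %s", paste(lv, collapse = "/"))
  }
  o <- order(along_track)
  out <- data.frame(along_track = along_track[o], elevation = elevation[o],
                    true_label = true_label[o],
                    pred_label = rep("unclassified", n),
                    stringsAsFactors = FALSE)
  class(out) <- c("photon_cloud", "data.frame")
  out
}

#' Simulate photon transects for a synthetic scene
#'
#' One transect per ground track: dense ground returns along the terrain
#' profile, canopy returns distributed through the crown depth at a rate
#' growing with LAI, and uniform background noise over the elevation search
#' window.  A simplified stand-in for photon-counting altimeter data.
#'
#' @param scene a `synthetic_scene`.
#' @param config a [scene_config].
#' @return list of `photon_cloud` objects, one per track.
#' @export
simulate_photon_transects <- function(scene, config) {
  width <- config$cols * config$pixel_size
  height <- config$rows * config$pixel_size
  track_x <- seq(config$track_spacing / 2, width - 1e-9,
                 by = config$track_spacing)
  with_seed(derive_seed(config$seed, 7L), {
    lapply(seq_along(track_x), function(ti) {
      tx <- track_x[ti]
      at_g <- seq(0.5, height - 0.5, by = 2)        # ground sampling, 2 m
      px <- point_to_pixel(rep(tx, length(at_g)), at_g, config$pixel_size,
                           config$rows, config$cols)
      terr <- scene$terrain[cbind(px$row, px$col)]
      can <- scene$canopy_height[cbind(px$row, px$col)]
      lai <- scene$lai_truth[cbind(px$row, px$col)]
      g_el <- terr + rnorm(length(at_g), sd = 0.1)
      # canopy photons: Poisson-ish thinning by LAI, uniform in crown depth
      keep <- runif(length(at_g)) < pmin(lai / 4, 0.95)
      idx <- which(keep & can > 2)
      c_at <- at_g[idx] + runif(length(idx), -1, 1)
      c_el <- terr[idx] + runif(length(idx), 0.25, 1) * can[idx]
      # background noise over the full search window
      n_noise <- rpois(1, 0.05 * height)
      n_at <- runif(n_noise, 0, height)
      lo <- min(terr) - 20
      hi <- max(terr + can) + 30
      n_el <- runif(n_noise, lo, hi)
      photon_cloud(
        along_track = c(at_g, c_at, n_at),
        elevation = c(g_el, c_el, n_el),
        true_label = c(rep("ground", length(at_g)),
                       rep("canopy", length(c_at)),
                       rep("noise", n_noise))
      )
    })
  })
}

#' Directional-density photon denoising
#'
#' Each photon is scored by the maximum, over 8 orientations spanning 180
#' degrees, of the photon count inside a rotated elliptical neighborhood
#' (semi-axes `radius_at` along, `radius_elev` across); photons whose score
#' falls below the `density_quantile` of all scores are removed.  A
#' simplified stand-in for density-based photon-cloud denoisers.
#'
#' @param cloud a [photon_cloud].
#' @param radius_at ellipse semi-axis along-track, m.
#' @param radius_elev ellipse semi-axis in elevation, m.
#' @param density_quantile fraction of lowest-scoring photons removed
#'   (0 keeps everything).
#' @return the retained [photon_cloud] with a `density_score` column.
#' @export
denoise_photons <- function(cloud, radius_at = 15, radius_elev = 3,
                            density_quantile = 0.1) {
  n <- nrow(cloud)
  if (n == 0) stopf("empty photon cloud")
  if (radius_at <= 0 || radius_elev <= 0) stopf("radii must be positive")
  score <- rep(0, n)
  angles <- seq(0, pi, length.out = 9)[1:8]
  dx <- outer(cloud$along_track, cloud$along_track, `-`)
  dz <- outer(cloud$elevation, cloud$elevation, `-`)
  for (a in angles) {
    u <- (dx * cos(a) + dz * sin(a)) / radius_at
    v <- (-dx * sin(a) + dz * cos(a)) / radius_elev
    cnt <- rowSums(u * u + v * v <= 1) - 1 # exclude self
    score <- pmax(score, cnt)
  }
  thr <- quantile(score, density_quantile, type = 1)
  keep <- score >= thr
  if (!any(keep)) {
    warning("denoise_photons removed every photon")
  }
  out <- cloud[keep, , drop = FALSE]
  out$density_score <- score[keep]
  class(out) <- class(cloud)
  out
}

#' Progressive-densification parameters
#'
#' @param window seed-selection window, m.
#' @param Di_threshold admission distance to the nearest seed ground
#'   photons, m.
#' @param At_threshold admission angle to the local ground line, degrees.
#' @param Ds_threshold final ground/canopy split: vertical distance to the
#'   fitted ground spline, m.
#' @param Di_sweep candidate admission distances, m.
#' @param selected_threshold the admission distance actually used, m.
#' @param max_iterations densification iteration cap.
#' @param dp_tolerance Douglas-Peucker simplification tolerance, m.
#' @return a `ptd_params` list.
#' @export
ptd_params <- function(window = 200, Di_threshold = NULL, At_threshold = 15,
                       Ds_threshold = 1, Di_sweep = seq(10, 50, by = 10),
                       selected_threshold = 20, max_iterations = 50,
                       dp_tolerance = 1) {
  if (window <= 0) stopf("window must be positive")
  if (Ds_threshold <= 0) stopf("Ds_threshold must be positive")
  if (!length(Di_sweep) || is.unsorted(Di_sweep)) {
    stopf("Di_sweep must be non-empty ascending")
  }
  if (is.null(Di_threshold)) Di_threshold <- selected_threshold
  structure(list(window = window, Di_threshold = Di_threshold,
                 At_threshold = At_threshold, Ds_threshold = Ds_threshold,
                 Di_sweep = Di_sweep,
                 selected_threshold = selected_threshold,
                 max_iterations = max_iterations,
                 dp_tolerance = dp_tolerance),
            class = "ptd_params")
}

#' Lowest-elevation seed photons per window
#'
#' @param cloud a denoised [photon_cloud].
#' @param window window length along track, m.
#' @return integer row indices of the seed photons, sorted by along-track
#'   position.
#' @export
find_ground_seeds <- function(cloud, window = 200) {
  if (!nrow(cloud)) return(integer(0))
  bin <- floor(cloud$along_track / window)
  idx <- tapply(seq_len(nrow(cloud)), bin, function(i) {
    i[which.min(cloud$elevation[i])]
  })
  sort(unname(unlist(idx)))
}

# perpendicular-distance Douglas-Peucker on an (x, y) polyline; returns
# indices of the retained vertices
douglas_peucker <- function(x, y, tol) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len <- sqrt(dx^2 + dy^2)
    ids <- (i + 1):(j - 1)
    d <- if (len == 0) {
      sqrt((x[ids] - x[i])^2 + (y[ids] - y[i])^2)
    } else {
      abs(dx * (y[i] - y[ids]) - dy * (x[i] - x[ids])) / len
    }
    k <- ids[which.max(d)]
    if (max(d) > tol) {
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  which(keep)
}

# fit the ground surface spline through (at, elev) support points; values
# are clamped to the cloud's elevation range so the surface cannot
# overshoot the data
ground_spline <- function(at, elev, clamp_range) {
  o <- order(at)
  at <- at[o]; elev <- elev[o]
  keep <- !duplicated(at)
  f <- splinefun(at[keep], elev[keep], method = "natural")
  function(x) pmin(pmax(f(x), clamp_range[1]), clamp_range[2])
}

#' Progressive densification ground/canopy classification
#'
#' Starting from lowest-elevation window seeds, repeatedly admits
#' unclassified photons whose distance `Di` to the two nearest seed ground
#' photons and angle `At` to the local ground line fall under the
#' thresholds, until no new seeds appear.  The seed polyline is then
#' simplified (Douglas-Peucker) and a cubic spline fitted through it; the
#' final rule labels a photon ground iff its vertical distance `Ds` to the
#' spline is below `Ds_threshold`, else canopy.
#'
#' @param cloud a denoised [photon_cloud].
#' @param params a [ptd_params].
#' @return the cloud with `pred_label` filled in; the fitted ground spline
#'   is attached as attribute `"ground_spline"`.
#' @export
classify_ptd <- function(cloud, params = ptd_params()) {
  n <- nrow(cloud)
  at <- cloud$along_track
  el <- cloud$elevation
  seeds <- find_ground_seeds(cloud, params$window)
  if (!length(seeds)) stopf("no seed ground photons found")
  is_seed <- rep(FALSE, n)
  is_seed[seeds] <- TRUE
  for (it in seq_len(params$max_iterations)) {
    sid <- which(is_seed)
    s_at <- at[sid]
    s_el <- el[sid]
    o <- order(s_at)
    s_at <- s_at[o]; s_el <- s_el[o]; sid <- sid[o]
    cand <- which(!is_seed)
    if (!length(cand)) break
    pos <- findInterval(at[cand], s_at)
    i1 <- pmax(pos, 1L)
    i2 <- pmin(pos + 1L, length(s_at))
    d1 <- sqrt((at[cand] - s_at[i1])^2 + (el[cand] - s_el[i1])^2)
    d2 <- sqrt((at[cand] - s_at[i2])^2 + (el[cand] - s_el[i2])^2)
    Di <- pmin(d1, d2)
    # local ground line through the two bracketing seeds
    gdx <- s_at[i2] - s_at[i1]
    gdy <- s_el[i2] - s_el[i1]
    near_at <- ifelse(d1 <= d2, s_at[i1], s_at[i2])
    near_el <- ifelse(d1 <= d2, s_el[i1], s_el[i2])
    vdx <- at[cand] - near_at
    vdy <- el[cand] - near_el
    glen <- sqrt(gdx^2 + gdy^2)
    vlen <- sqrt(vdx^2 + vdy^2)
    cosang <- ifelse(glen > 0 & vlen > 0,
                     pmin(abs(gdx * vdx + gdy * vdy) / (glen * vlen), 1),
                     1) # degenerate geometry: do not block on the angle
    At <- acos(cosang) * 180 / pi
    admit <- Di <= params$Di_threshold & At <= params$At_threshold
    if (!any(admit)) break
    is_seed[cand[admit]] <- TRUE
  }
  sid <- which(is_seed)
  if (length(sid) < 4) {
    stopf("classification failure: only %d ground photons, cannot fit %s",
          length(sid), "the ground spline")
  }
  o <- order(at[sid])
  sx <- at[sid][o]; sy <- el[sid][o]
  # despike the seed polyline before simplification: canopy contaminants
  # are upward outliers against the local seed median, and line
  # simplification would otherwise retain exactly those maximal deviations
  if (length(sx) >= 8) {
    med <- vapply(seq_along(sx), function(i) {
      w <- abs(sx - sx[i]) <= params$window / 8
      median(sy[w])
    }, 0)
    keep_seed <- abs(sy - med) <= 2 * params$Ds_threshold
    if (sum(keep_seed) >= 4) {
      sx <- sx[keep_seed]
      sy <- sy[keep_seed]
    }
  }
  dpk <- douglas_peucker(sx, sy, params$dp_tolerance)
  if (length(dpk) < 4) dpk <- seq_along(sx)
  spl <- ground_spline(sx[dpk], sy[dpk], range(el))
  ds <- abs(el - spl(at))
  cloud$pred_label <- ifelse(ds < params$Ds_threshold, "ground", "canopy")
  attr(cloud, "ground_spline") <- spl
  cloud
}

#' Per-segment footprint attributes from a classified photon cloud
#'
#' Splits the transect into fixed-length segments and reports, per segment:
#' `h_te_best_fit` (robust least-squares line through the segment's ground
#' photons after 2-sigma elevation clipping, evaluated at the segment
#' center), `h_te_interp` (ground-spline value at the center) and
#' `h_mean_canopy_abs` (mean canopy elevation above the spline).  Segments
#' without ground photons carry `NA` attributes.
#'
#' @param classified output of [classify_ptd()].
#' @param segment segment length, m (default 100).
#' @return a `footprint_segment_table` data frame.
#' @export
extract_footprint_metrics <- function(classified, segment = 100) {
  if (!"pred_label" %in% names(classified) ||
      all(classified$pred_label == "unclassified")) {
    stopf("run classify_ptd first")
  }
  spl <- attr(classified, "ground_spline")
  if (is.null(spl)) {
    g <- classified$pred_label == "ground"
    spl <- ground_spline(classified$along_track[g],
                         classified$elevation[g],
                         range(classified$elevation))
  }
  at <- classified$along_track
  n_seg <- ceiling(max(at) / segment)
  rows <- lapply(seq_len(n_seg), function(k) {
    lo <- (k - 1) * segment
    hi <- k * segment
    center <- (lo + hi) / 2
    in_seg <- at >= lo & at < hi
    g <- in_seg & classified$pred_label == "ground"
    cny <- in_seg & classified$pred_label == "canopy"
    if (!any(g)) {
      return(data.frame(segment_id = k, center_m = center,
                        h_te_best_fit = NA_real_, h_te_interp = NA_real_,
                        h_mean_canopy_abs = NA_real_,
                        n_ground = 0L, n_canopy = sum(cny)))
    }
    gx <- at[g]; gy <- classified$elevation[g]
    if (length(gx) >= 3) {
      mu <- mean(gy); sdev <- sd(gy)
      keep <- if (is.finite(sdev) && sdev > 0) abs(gy - mu) <= 2 * sdev
              else rep(TRUE, length(gy))
      gx2 <- gx[keep]; gy2 <- gy[keep]
    } else {
      gx2 <- gx; gy2 <- gy
    }
    bf <- if (length(unique(gx2)) >= 2) {
      cf <- stats::coef(stats::lm(gy2 ~ gx2))
      unname(cf[1] + cf[2] * center)
    } else {
      mean(gy2)
    }
    hcan <- if (any(cny)) {
      mean(classified$elevation[cny] - spl(at[cny]))
    } else {
      NA_real_
    }
    data.frame(segment_id = k, center_m = center, h_te_best_fit = bf,
               h_te_interp = spl(center), h_mean_canopy_abs = hcan,
               n_ground = sum(g), n_canopy = sum(cny))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("footprint_segment_table", "data.frame")
  out
}
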