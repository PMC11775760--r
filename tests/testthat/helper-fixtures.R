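# shared fixtures, all generated in code (no stored data)

# small scene used across module tests
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scene_config(rows = 48, cols = 48, pixel_size = 15,
                          plot_count = 20, track_spacing = 180, seed = 42)
      cache <<- generate_scene(cfg, photons = FALSE)
    }
    cache
  }
})

# unit-square point set with a known spherical structure (for geostats)
sim_field_points <- function(seed, n = 2000, rows = 128, cols = 128,
                             nugget = 0.1, psill = 0.9, range_a = 30) {
  cfg <- scene_config(rows = rows, cols = cols, pixel_size = 1,
                      lai_mean = 10, lai_sd = 1,
                      truth_variogram = variogram_model("spherical", nugget,
                                                        psill, range_a),
                      seed = seed)
  f <- generate_gaussian_field(cfg)
  idx <- with_seed(seed, sample(length(f), n))
  rc <- arrayInd(idx, dim(f))
  point_samples(rc[, 2] - 0.5, rc[, 1] - 0.5, f[idx])
}

# brute-force O(n^2) semivariogram oracle (mirrors the production binning)
brute_variogram <- function(pts, lag_width, max_lag) {
  n <- nrow(pts)
  nbin <- ceiling(max_lag / lag_width)
  gsum <- hsum <- cnt <- numeric(nbin)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
      if (h >= max_lag) next
      b <- floor(h / lag_width) + 1
      gsum[b] <- gsum[b] + (pts$value[i] - pts$value[j])^2
      hsum[b] <- hsum[b] + h
      cnt[b] <- cnt[b] + 1
    }
  }
  data.frame(
    lag = ifelse(cnt > 0, hsum / cnt, (seq_len(nbin) - 0.5) * lag_width),
    gamma = ifelse(cnt > 0, gsum / (2 * cnt), NA_real_),
    n_pairs = cnt)
}

# exhaustive GLCM oracle: explicit pair enumeration on a quantized matrix
glcm_oracle <- function(q, levels, window, orientations, symmetric,
                        center) {
  half <- window %/% 2
  nr <- nrow(q); nc <- ncol(q)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))
  P <- matrix(0, levels, levels)
  for (a in orientations) {
    d <- offs[[as.character(a)]]
    for (wr in -half:half) {
      for (wc in -half:half) {
        wr2 <- wr + d[1]; wc2 <- wc + d[2]
        if (abs(wr2) > half || abs(wc2) > half) next
        i <- q[reflect(center[1] + wr, nr), reflect(center[2] + wc, nc)]
        j <- q[reflect(center[1] + wr2, nr), reflect(center[2] + wc2, nc)]
        P[i + 1, j + 1] <- P[i + 1, j + 1] + 1
        if (symmetric) P[j + 1, i + 1] <- P[j + 1, i + 1] + 1
      }
    }
  }
  P <- P / sum(P)
  iv <- matrix(0:(levels - 1), levels, levels)
  jv <- t(iv)
  mi <- sum(iv * P); mj <- sum(jv * P)
  vi <- sum((iv - mi)^2 * P); vj <- sum((jv - mj)^2 * P)
  ent <- -sum(ifelse(P > 0, P * log(P), 0))
  list(Mean = mi, Variance = vi,
       Homogeneity = sum(P / (1 + (iv - jv)^2)),
       Contrast = sum(P * (iv - jv)^2),
       Dissimilarity = sum(P * abs(iv - jv)),
       Entropy = ent, SecondMoment = sum(P^2),
       Correlation = if (vi > 0 && vj > 0)
         sum(P * (iv - mi) * (jv - mj)) / sqrt(vi * vj) else 0,
       Psum = sum(P))
}

# linear toy regression data
toy_xy <- function(n = 40, p = 4, seed = 1, noise = 0.3) {
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    x2 <- if (p >= 2) X[, 2] else 0
    list(X = X, y = 2 + X[, 1] + 0.5 * x2 + noise * rnorm(n))
  })
}

# 4-D sphere surrogate space for optimizer tests
sphere_space <- function(d = 4, low = -5, high = 5) {
  structure(data.frame(name = paste0("x", seq_len(d)), kind = "continuous",
                       low = low, high = high),
            class = c("search_space", "data.frame"))
}

# build a feature table with a predictor of exact target correlation
exact_r_table <- function(r_targets, n = 51, seed = 4) {
  with_seed(seed, {
    y <- rnorm(n)
    y <- (y - mean(y)) / sd(y)
    out <- data.frame(lai = y + 5) # positive response
    for (k in seq_along(r_targets)) {
      e <- rnorm(n)
      e <- stats::resid(stats::lm(e ~ y))
      e <- e / sd(e)
      r <- r_targets[k]
      out[[paste0("p", k)]] <- r * y + sqrt(1 - r^2) * e
    }
    out
  })
}

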