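#' Point samples for geostatistical analysis
#'
#' Bundles planar coordinates (metres) with one attribute value per point.
#' Duplicate coordinates are averaged on construction, mirroring the usual
#' pre-processing of altimeter footprints stacked on repeated tracks.
#'
#' @param x,y numeric coordinates in metres.
#' @param value numeric attribute values.
#' @return a `point_samples` data frame with columns `x`, `y`, `value`.
#' @export
point_samples <- function(x, y, value) {
  if (length(x) != length(y) || length(x) != length(value)) {
    stopf("x, y and value must have equal length")
  }
  keep <- is.finite(x) & is.finite(y) & is.finite(value)
  if (!all(keep)) {
    log_msg("dropping %d non-finite point(s)", sum(!keep))
    x <- x[keep]; y <- y[keep]; value <- value[keep]
  }
  key <- paste(x, y, sep = "_")
  if (anyDuplicated(key)) {
    value <- as.numeric(tapply(value, key, mean))
    x <- as.numeric(tapply(x, key, `[`, 1L))
    y <- as.numeric(tapply(y, key, `[`, 1L))
  }
  out <- data.frame(x = x, y = y, value = value)
  class(out) <- c("point_samples", "data.frame")
  out
}

#' Min-max normalization to [0, 1]
#'
#' `Y = (y - ymin) / (ymax - ymin)`, with the bounds stored so the mapping
#' can be inverted after analysis.
#'
#' @param values numeric vector.
#' @return list with `values` (normalized), `ymin`, `ymax`.
#' @export
minmax_normalize <- function(values) {
  ymin <- min(values)
  ymax <- max(values)
  if (!(ymax > ymin)) stopf("degenerate range: all values equal (%g)", ymin)
  list(values = (values - ymin) / (ymax - ymin), ymin = ymin, ymax = ymax)
}

#' Invert a min-max normalization
#' @param values normalized values in [0, 1].
#' @param ymin,ymax original data bounds.
#' @return values on the original scale.
#' @export
minmax_denormalize <- function(values, ymin, ymax) {
  values * (ymax - ymin) + ymin
}

#' Shapiro-Wilk normality decision at alpha = 0.05
#'
#' @param values numeric vector, n >= 8.
#' @return list with `decision` ("normal"/"non_normal"), `statistic`,
#'   `p_value`.
#' @export
normality_check <- function(values) {
  if (length(values) < 8) stopf("normality_check needs n >= 8")
  # shapiro.test caps n at 5000; subsample deterministically beyond that
  v <- values
  if (length(v) > 5000) {
    v <- v[round(seq(1, length(v), length.out = 5000))]
  }
  st <- shapiro.test(v)
  list(decision = if (st$p.value >= 0.05) "normal" else "non_normal",
       statistic = unname(st$statistic), p_value = st$p.value)
}

#' Signed cube-root transform
#' @param values numeric vector.
#' @return `sign(values) * abs(values)^(1/3)`.
#' @export
cube_root_transform <- function(values) {
  sign(values) * abs(values)^(1 / 3)
}

#' Empirical (experimental) semivariogram
#'
#' Computes `gamma(h) = (1 / (2 n(h))) * sum [Z(x_i + h) - Z(x_i)]^2` with
#' pairs binned by Euclidean separation into `[k * lag_width,
#' (k + 1) * lag_width)`.
#'
#' @param points a [point_samples] table.
#' @param lag_width bin width in metres.
#' @param max_lag maximum pair separation considered, metres.
#' @return an `empirical_variogram` data frame with columns `lag`
#'   (mean pair distance per bin), `gamma` and `n_pairs`; empty bins carry
#'   `NA` semivariance.
#' @export
empirical_variogram <- function(points, lag_width, max_lag) {
  if (nrow(points) < 2) stopf("need at least 2 points")
  if (lag_width <= 0) stopf("lag_width must be positive")
  res <- cpp_empirical_variogram(points$x, points$y, points$value,
                                 lag_width, max_lag)
  if (all(res$n_pairs == 0)) stopf("no point pairs within max_lag = %g",
                                   max_lag)
  out <- data.frame(lag = res$lag, gamma = res$gamma, n_pairs = res$n_pairs)
  attr(out, "lag_width") <- lag_width
  attr(out, "max_lag") <- max_lag
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

.vgm_kinds <- c(spherical = 1L, exponential = 2L, gaussian = 3L)

#' Construct a theoretical variogram model
#'
#' Effective-range parameterization: the exponential model is
#' `C0 + C (1 - exp(-3h/a))` and the Gaussian `C0 + C (1 - exp(-3h^2/a^2))`,
#' so `a` is the distance at which ~95% of the sill is reached for all three
#' kinds (GS+ convention).
#'
#' @param kind one of "spherical", "exponential", "gaussian".
#' @param nugget nugget variance `C0 >= 0`.
#' @param psill partial sill `C >= 0`; the sill is `C0 + C`.
#' @param range_a effective range in metres, `> 0`.
#' @param fit_R2,fit_RSS optional goodness-of-fit statistics.
#' @return a `variogram_model` object.
#' @export
variogram_model <- function(kind, nugget, psill, range_a,
                            fit_R2 = NA_real_, fit_RSS = NA_real_) {
  kind <- match.arg(kind, names(.vgm_kinds))
  if (nugget < 0 || psill < 0) stopf("nugget and partial sill must be >= 0")
  if (!(range_a > 0)) stopf("range must be positive")
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 sill = nugget + psill, range_a = range_a,
                 fit_R2 = fit_R2, fit_RSS = fit_RSS),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "variogram_model: %s  C0=%.4g  C0+C=%.4g  range=%.4g  R2=%.4g\n",
    x$kind, x$nugget, x$sill, x$range_a, x$fit_R2))
  invisible(x)
}

#' Evaluate a theoretical variogram model
#'
#' `gamma(0) = 0` by convention; the nugget appears as the limit from the
#' right.
#'
#' @param model a [variogram_model].
#' @param h non-negative lag distance(s), metres.
#' @return semivariance at `h`.
#' @export
variogram_model_value <- function(model, h) {
  if (any(h < 0)) stopf("negative lag distance")
  u <- h / model$range_a
  g <- switch(model$kind,
    spherical = ifelse(u < 1, 1.5 * u - 0.5 * u^3, 1),
    exponential = 1 - exp(-3 * u),
    gaussian = 1 - exp(-3 * u^2)
  )
  ifelse(h == 0, 0, model$nugget + model$psill * g)
}

#' Fit theoretical variogram models to an empirical variogram
#'
#' Weighted least squares (weights = pair counts) over `(C0, C, a)` for each
#' requested model kind, ranked by fit R-squared (ties broken by lower RSS),
#' emulating the usual best-model choice of variogram software.
#'
#' @param emp an [empirical_variogram].
#' @param kinds model kinds to try.
#' @return list of [variogram_model] objects sorted best-first.
#' @export
fit_variogram <- function(emp,
                          kinds = c("spherical", "exponential", "gaussian")) {
  ok <- is.finite(emp$gamma) & emp$n_pairs > 0
  if (sum(ok) < 4) stopf("need >= 4 non-empty lag bins, have %d", sum(ok))
  h <- emp$lag[ok]
  g <- emp$gamma[ok]
  w <- emp$n_pairs[ok]
  max_lag <- attr(emp, "max_lag")
  if (is.null(max_lag)) max_lag <- max(h)
  wmean <- sum(w * g) / sum(w)
  tss <- sum(w * (g - wmean)^2)
  fits <- list()
  for (kind in kinds) {
    obj <- function(par) {
      m <- variogram_model(kind, par[1], par[2], par[3])
      sum(w * (variogram_model_value(m, h) - g)^2)
    }
    # multi-start around moment-based guesses
    g0 <- max(min(g[1], wmean), 0)
    starts <- list(
      c(g0 * 0.5, max(wmean - g0 * 0.5, 1e-8), max(h) / 2),
      c(1e-8, max(wmean, 1e-8), max(h) / 3),
      c(g0 * 0.5, max(wmean - g0 * 0.5, 1e-8), max(h))
    )
    best <- NULL
    for (st in starts) {
      res <- tryCatch(
        optim(st, obj, method = "L-BFGS-B",
              lower = c(0, 0, max(h) * 1e-3),
              upper = c(Inf, Inf, 2 * max_lag)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    if (is.null(best)) {
      warning(sprintf("variogram fit failed for kind '%s'; skipped", kind))
      next
    }
    rss <- best$value
    r2 <- if (tss > 0) 1 - rss / tss else 0
    m <- variogram_model(kind, best$par[1], best$par[2], best$par[3],
                         fit_R2 = r2, fit_RSS = rss)
    if (tss <= 0) attr(m, "degenerate") <- TRUE
    fits[[kind]] <- m
  }
  if (!length(fits)) stopf("all variogram model fits failed")
  r2s <- vapply(fits, function(m) m$fit_R2, 0)
  rsss <- vapply(fits, function(m) m$fit_RSS, 0)
  fits[order(-r2s, rsss)]
}

#' Variogram analysis report
#'
#' One row per fitted model with the columns variogram software typically
#' prints: model kind, R2, RSS, nugget, sill, nugget ratio `C0/(C0+C)` and
#' range.  The ratio is reported without interpretation.
#'
#' @param fits list returned by [fit_variogram()].
#' @param path optional JSON output path.
#' @return data frame (invisibly written to `path` when given).
#' @export
variogram_report <- function(fits, path = NULL) {
  df <- do.call(rbind, lapply(fits, function(m) {
    data.frame(Model = m$kind, R2 = m$fit_R2, RSS = m$fit_RSS,
               C0 = m$nugget, sill = m$sill,
               nugget_ratio = if (m$sill > 0) m$nugget / m$sill else NA_real_,
               Range = m$range_a)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  }
  df
}
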