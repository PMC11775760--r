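#' Grid geometry helper
#'
#' @param nrow,ncol grid dimensions (pixels).
#' @param pixel_size pixel edge length in metres.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(nrow, ncol, pixel_size = 15) {
  if (nrow < 1 || ncol < 1 || pixel_size <= 0) stopf("invalid grid spec")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size),
            class = "grid_spec")
}

#' Simple kriging on a regular grid
#'
#' Solves, per node, the simple-kriging system built from the covariance
#' `C(h) = sill - gamma(h)` over the nearest conditioning points, assuming a
#' known mean (0, the normal-score convention).  Estimates are
#' `mean + sum(lambda_i (z_i - mean))` and variances
#' `sill - sum(lambda_i C(h_i0))`.
#'
#' @param data a [point_samples] table (typically normal scores, mean 0).
#' @param model a [variogram_model].
#' @param grid a [grid_spec].
#' @param neighbors number of nearest conditioning points per node.
#' @param sk_mean known stationary mean (default 0).
#' @return list with matrices `estimate` and `variance`, plus `n_jitter`
#'   (count of singular systems stabilized by a `1e-10 * sill` diagonal
#'   jitter).
#' @export
simple_kriging <- function(data, model, grid, neighbors = 16, sk_mean = 0) {
  if (neighbors < 1) stopf("neighbors must be >= 1")
  res <- cpp_sk_grid(data$x, data$y, data$value - sk_mean,
                     grid$nrow, grid$ncol, grid$pixel_size,
                     model$nugget, model$psill, model$range_a,
                     .vgm_kinds[[model$kind]], as.integer(neighbors))
  if (res$n_jitter > 0) {
    log_msg("simple_kriging: %d singular system(s) jittered", res$n_jitter)
  }
  list(estimate = res$estimate + sk_mean, variance = res$variance,
       n_jitter = res$n_jitter)
}

#' Sequential Gaussian conditional simulation
#'
#' Per realization: normal-score transform the data, visit the free grid
#' nodes along a seeded random path, simple-krige each node from the nearest
#' conditioning values (original data plus previously simulated nodes), draw
#' from `Normal(SK mean, SK variance)`, then back-transform through the
#' inverse normal-score map (linear interpolation, linear tail
#' extrapolation).  Data falling inside a pixel are pinned to that node
#' (averaged when several share a pixel) so realizations honor the
#' conditioning data exactly.
#'
#' @param data a [point_samples] table on the original attribute scale.
#' @param model a [variogram_model] fitted on normal scores.
#' @param grid a [grid_spec].
#' @param n_realizations number of equiprobable realizations (>= 1).
#' @param neighbors conditioning neighborhood size.
#' @param seed root seed; realization sub-seeds are split from it with
#'   [derive_seed()].
#' @param node_budget guard on `n_realizations * nodes` (default 5e7).
#' @param keep_gaussian also return the normal-score realizations.
#' @return an `sgcs_ensemble`: list with `realizations` (array
#'   rows x cols x n), `mean_surface`, `pixel_cv` (pixelwise coefficient of
#'   variation, sd/|mean|), `n_realizations`, `seed`, `ns_map`, and
#'   optionally `gaussian` realizations.
#' @export
sgcs <- function(data, model, grid, n_realizations = 25, neighbors = 16,
                 seed = 1, node_budget = 5e7, keep_gaussian = FALSE) {
  if (n_realizations < 1) stopf("n_realizations must be >= 1")
  nodes <- grid$nrow * grid$ncol
  if (as.double(n_realizations) * nodes > node_budget) {
    stopf(paste0("simulation budget exceeded (%g nodes requested, budget ",
                 "%g); use a smaller grid or fewer realizations"),
          as.double(n_realizations) * nodes, node_budget)
  }
  nsm <- normal_score_map(data$value)
  zval <- ns_forward(nsm, data$value)
  # pin data that fall on grid nodes (half-open pixel ownership)
  px <- point_to_pixel(data$x, data$y, grid$pixel_size, grid$nrow, grid$ncol)
  fixed <- rep(NA_real_, nodes)
  on_grid <- px$inside
  if (any(on_grid)) {
    j <- (px$col[on_grid] - 1L) * grid$nrow + (px$row[on_grid] - 1L) # 0-based
    agg <- tapply(zval[on_grid], j, mean)
    fixed[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  free_idx <- which(is.na(fixed)) - 1L # 0-based, column-major
  stack <- array(NA_real_, dim = c(grid$nrow, grid$ncol, n_realizations))
  gstack <- if (keep_gaussian) stack else NULL
  for (r in seq_len(n_realizations)) {
    sub <- derive_seed(seed, r)
    sim <- with_seed(sub, {
      path <- free_idx[sample.int(length(free_idx))]
      noise <- rnorm(length(free_idx))
      cpp_sgcs_realization(data$x, data$y, zval, grid$nrow, grid$ncol,
                           grid$pixel_size, fixed, path, noise,
                           model$nugget, model$psill, model$range_a,
                           .vgm_kinds[[model$kind]], as.integer(neighbors))
    })
    if (keep_gaussian) gstack[, , r] <- sim
    stack[, , r] <- matrix(ns_inverse(nsm, sim), grid$nrow, grid$ncol)
  }
  mean_surface <- apply(stack, c(1, 2), mean)
  if (n_realizations > 1) {
    sds <- apply(stack, c(1, 2), sd)
    pixel_cv <- sds / pmax(abs(mean_surface), .Machine$double.eps)
  } else {
    pixel_cv <- matrix(NA_real_, grid$nrow, grid$ncol)
  }
  structure(list(realizations = stack, mean_surface = mean_surface,
                 pixel_cv = pixel_cv, n_realizations = n_realizations,
                 seed = seed, ns_map = nsm, grid = grid,
                 gaussian = gstack),
            class = "sgcs_ensemble")
}

#' Choose the realization count from a coefficient-of-variation sweep
#'
#' Simulates `max(counts)` realizations once, computes the mean pixel CV of
#' each nested prefix (so the sweep shares one reproducible realization
#' stream), and selects the smallest count whose relative change in mean CV
#' from the previous count falls below `tol`.
#'
#' @param data,model,grid,neighbors,seed as in [sgcs()].
#' @param counts ascending realization counts to examine.
#' @param tol stabilization threshold on the relative CV change
#'   (default 0.05).
#' @return list with `selected`, `cv_curve` (data frame count/mean_cv) and
#'   the full [sgcs()] ensemble at `max(counts)`.
#' @export
choose_realization_count <- function(data, model, grid,
                                     counts = c(1, 10, 25, 50, 75, 100),
                                     neighbors = 16, seed = 1, tol = 0.05) {
  if (is.unsorted(counts, strictly = TRUE)) {
    stopf("counts must be strictly ascending")
  }
  ens <- sgcs(data, model, grid, n_realizations = max(counts),
              neighbors = neighbors, seed = seed)
  mean_cv <- vapply(counts, function(k) {
    if (k < 2) return(NA_real_)
    sub <- ens$realizations[, , seq_len(k), drop = FALSE]
    mu <- apply(sub, c(1, 2), mean)
    sds <- apply(sub, c(1, 2), sd)
    mean(sds / pmax(abs(mu), .Machine$double.eps))
  }, 0)
  cv_curve <- data.frame(count = counts, mean_cv = mean_cv)
  selected <- NA_integer_
  for (i in seq_along(counts)[-1]) {
    if (is.na(mean_cv[i - 1]) || is.na(mean_cv[i])) next
    rel <- abs(mean_cv[i] - mean_cv[i - 1]) /
      pmax(abs(mean_cv[i - 1]), .Machine$double.eps)
    if (rel < tol) {
      selected <- counts[i]
      break
    }
  }
  if (length(counts) == 1L) {
    selected <- counts[1]
    log_msg("single-count sweep: CV undefined at one realization")
  }
  list(selected = selected, cv_curve = cv_curve, ensemble = ens)
}

#' Interpolation fidelity of a surface at its conditioning points
#'
#' R-squared (coefficient-of-determination form) between point values and
#' the surface values at the pixels containing the points.
#'
#' @param points a [point_samples] table.
#' @param surface numeric matrix on `grid`.
#' @param grid a [grid_spec].
#' @return R2 (can be negative for surfaces worse than the mean).
#' @export
interpolation_fidelity <- function(points, surface, grid) {
  if (nrow(points) < 3) stopf("need >= 3 points")
  px <- point_to_pixel(points$x, points$y, grid$pixel_size,
                       grid$nrow, grid$ncol)
  if (!all(px$inside)) stopf("all points must lie inside the grid")
  shat <- surface[cbind(px$row, px$col)]
  y <- points$value
  1 - sum((y - shat)^2) / sum((y - mean(y))^2)
}
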