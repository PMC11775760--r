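test_that("min-max normalization matches the closed form and inverts", {
  nm <- minmax_normalize(c(2, 4, 6))
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(minmax_denormalize(c(0.3, 0.7), 10, 20), c(13, 17))
  expect_equal(minmax_normalize(c(5, 9))$values[1], 0) # y = ymin -> 0
  expect_error(minmax_normalize(rep(3, 4)), "degenerate")
})

test_that("normality decision and signed cube root", {
  expect_equal(cube_root_transform(-8), -2)
  expect_equal(cube_root_transform(c(27, 0)), c(3, 0))
  hits <- vapply(1:50, function(s) with_seed(s, {
    normality_check(rnorm(500))$decision == "normal"
  }), TRUE)
  expect_gte(mean(hits), 0.9)
  skewed <- with_seed(1, rlnorm(500))
  expect_equal(normality_check(skewed)$decision, "non_normal")
  expect_error(normality_check(1:5), "n >= 8")
})

test_that("empirical variogram equals the brute-force pair oracle", {
  # collinear worked example: values 0,1,2 at x = 0,1,2
  pts <- point_samples(c(0, 1, 2), c(0, 0, 0), c(0, 1, 2))
  emp <- empirical_variogram(pts, 1, 3)
  expect_equal(emp$gamma[emp$n_pairs > 0], c(0.5, 2))
  expect_equal(emp$n_pairs, c(0, 2, 1))

  # constant field
  cst <- point_samples(runif(30), runif(30), rep(5, 30))
  ec <- empirical_variogram(cst, 0.2, 1)
  expect_true(all(ec$gamma[ec$n_pairs > 0] == 0))

  # 200-point random set: exact match with the O(n^2) loop
  pts2 <- with_seed(8, point_samples(runif(200, 0, 50), runif(200, 0, 50),
                                     rnorm(200)))
  emp2 <- empirical_variogram(pts2, 5, 40)
  oracle <- brute_variogram(pts2, 5, 40)
  expect_equal(emp2$gamma, oracle$gamma, tolerance = 1e-12)
  expect_equal(emp2$lag, oracle$lag, tolerance = 1e-12)
  expect_equal(emp2$n_pairs, oracle$n_pairs)

  expect_error(empirical_variogram(point_samples(c(0, 100), c(0, 0),
                                                 c(1, 2)), 1, 5),
               "no point pairs")
})

test_that("theoretical variogram models take their closed forms", {
  sph <- variogram_model("spherical", 0.2, 0.8, 10)
  expect_equal(variogram_model_value(sph, 0), 0)
  expect_equal(variogram_model_value(sph, c(10, 15, 100)), rep(1, 3))
  expect_equal(variogram_model_value(sph, 5),
               0.2 + 0.8 * (1.5 * 0.5 - 0.5 * 0.125))
  ex <- variogram_model("exponential", 0.1, 0.9, 12)
  expect_equal(variogram_model_value(ex, 12), 0.1 + 0.9 * (1 - exp(-3)))
  ga <- variogram_model("gaussian", 0, 1, 12)
  expect_equal(variogram_model_value(ga, 12), 1 - exp(-3))
  expect_error(variogram_model_value(sph, -1), "negative")
})

test_that("variogram fitting recovers parameters and ranks by R2", {
  # exact-fit: empirical points lying on a spherical curve
  m0 <- variogram_model("spherical", 0.15, 0.85, 25)
  h <- seq(2, 50, by = 4)
  emp <- data.frame(lag = h, gamma = variogram_model_value(m0, h),
                    n_pairs = rep(100, length(h)))
  attr(emp, "max_lag") <- 50
  class(emp) <- c("empirical_variogram", "data.frame")
  fits <- fit_variogram(emp)
  expect_equal(fits[[1]]$kind, "spherical")
  expect_lte(fits[[1]]$fit_RSS, 1e-8)
  expect_gte(fits[[1]]$fit_R2, 1 - 1e-7)
  expect_equal(fits[[1]]$range_a, 25, tolerance = 1e-3)

  # degenerate: flat gamma -> R2 reported as 0 with flag
  flat <- data.frame(lag = h, gamma = rep(0.5, length(h)),
                     n_pairs = rep(10, length(h)))
  attr(flat, "max_lag") <- 50
  class(flat) <- c("empirical_variogram", "data.frame")
  ff <- fit_variogram(flat)
  expect_equal(ff[[1]]$fit_R2, 0)
  expect_true(isTRUE(attr(ff[[1]], "degenerate")))

  expect_error(fit_variogram(emp[1:3, ]), "4 non-empty")

  # report mirrors the analysis-table columns
  rep_df <- variogram_report(fits)
  expect_named(rep_df, c("Model", "R2", "RSS", "C0", "sill",
                         "nugget_ratio", "Range"))
})

test_that("normal-score transform round-trips and is monotone", {
  v <- with_seed(3, rlnorm(200))
  nsm <- normal_score_map(v)
  z <- ns_forward(nsm, v)
  expect_equal(ns_inverse(nsm, z), v, tolerance = 1e-9)
  expect_true(all(diff(ns_forward(nsm, sort(v))) >= 0))
  expect_true(all(diff(ns_inverse(nsm, seq(-3, 3, 0.1))) >= 0))
  # tails extrapolate linearly (finite, ordered)
  ex <- ns_inverse(nsm, c(-10, 10))
  expect_true(ex[1] < min(v) && ex[2] > max(v))
})

test_that("simple kriging: exactness, limits, dense-solve oracle", {
  m <- variogram_model("spherical", 0, 1, 30)
  g <- grid_spec(4, 4, 10)
  pts <- point_samples(c(5, 25, 35, 15, 5), c(5, 15, 35, 25, 35),
                       c(1.2, -0.4, 0.8, 0.1, -1))
  k <- simple_kriging(pts, m, g, neighbors = 5)
  # node coincident with a datum, nugget = 0: exact with zero variance
  expect_equal(k$estimate[1, 1], 1.2, tolerance = 1e-8)
  expect_equal(k$variance[1, 1], 0, tolerance = 1e-8)
  # variance bounded by the sill
  expect_true(all(k$variance >= 0 & k$variance <= m$sill + 1e-12))

  # far node tends to the SK mean (0) at full sill
  gfar <- grid_spec(1, 1, 1000)
  kf <- simple_kriging(pts, m, gfar, neighbors = 5)
  expect_equal(kf$estimate[1, 1], 0, tolerance = 1e-10)
  expect_equal(kf$variance[1, 1], m$sill, tolerance = 1e-10)

  # neighbor truncation at k = n equals a dense all-neighbor solve oracle
  dense <- function(pts, m, tx, ty) {
    n <- nrow(pts)
    A <- matrix(0, n, n)
    cov <- function(h) ifelse(h <= 0, m$sill, m$psill *
                                (1 - (variogram_model_value(m, h) -
                                        m$nugget) / m$psill))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      h <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
      A[i, j] <- m$sill - variogram_model_value(m, h)
    }
    diag(A) <- m$sill
    b <- vapply(seq_len(n), function(i) {
      h <- sqrt((pts$x[i] - tx)^2 + (pts$y[i] - ty)^2)
      m$sill - variogram_model_value(m, h)
    }, 0)
    lam <- solve(A, b)
    c(sum(lam * pts$value), m$sill - sum(lam * b))
  }
  o <- dense(pts, m, 15, 15) # center of pixel (2, 2)
  k22 <- simple_kriging(pts, m, g, neighbors = nrow(pts))
  expect_equal(k22$estimate[2, 2], o[1], tolerance = 1e-8)
  expect_equal(k22$variance[2, 2], o[2], tolerance = 1e-8)
})

test_that("SGCS honors data, reproduces itself under a seed and stays
           within the budget guard", {
  pts <- sim_field_points(21, n = 120, rows = 32, cols = 32, range_a = 10)
  m <- variogram_model("spherical", 0.05, 0.95, 10)
  g <- grid_spec(32, 32, 1)
  e1 <- sgcs(pts, m, g, n_realizations = 3, seed = 5)
  e2 <- sgcs(pts, m, g, n_realizations = 3, seed = 5)
  expect_identical(e1$realizations, e2$realizations)
  # conditioning: realizations equal the data at data pixels
  px <- laiscape:::point_to_pixel(pts$x, pts$y, 1, 32, 32)
  for (r in 1:3) {
    expect_lt(max(abs(e1$realizations[cbind(px$row, px$col, r)] -
                        pts$value)), 1e-6)
  }
  # mean surface consistency
  expect_equal(e1$mean_surface, apply(e1$realizations, c(1, 2), mean))
  # budget guard
  expect_error(sgcs(pts, m, g, n_realizations = 10, node_budget = 100),
               "budget")
  # single realization: CV undefined
  expect_true(all(is.na(sgcs(pts, m, g, n_realizations = 1,
                             seed = 1)$pixel_cv)))
})

test_that("realization-count sweep: forced ties give zero CV and single
           count is flagged", {
  pts <- sim_field_points(22, n = 80, rows = 24, cols = 24, range_a = 8)
  m <- variogram_model("spherical", 0.05, 0.95, 8)
  g <- grid_spec(24, 24, 1)
  cr1 <- choose_realization_count(pts, m, g, counts = 1, seed = 2)
  expect_equal(cr1$selected, 1)
  expect_true(is.na(cr1$cv_curve$mean_cv[1]))

  # two identical realizations (same sub-seed forced by stacking one twice)
  e <- sgcs(pts, m, g, n_realizations = 1, seed = 3)
  stack2 <- array(rep(e$realizations[, , 1], 2), c(24, 24, 2))
  sds <- apply(stack2, c(1, 2), sd)
  expect_true(all(sds == 0))
})

test_that("interpolation fidelity follows the R2 definition", {
  pts <- point_samples(c(5, 15, 25), c(5, 15, 25), c(1, 2, 3))
  g <- grid_spec(3, 3, 10)
  exact <- matrix(0, 3, 3)
  exact[cbind(c(1, 2, 3), c(1, 2, 3))] <- c(1, 2, 3)
  expect_equal(interpolation_fidelity(pts, exact, g), 1)
  expect_equal(interpolation_fidelity(pts, matrix(2, 3, 3), g), 0)
  expect_error(interpolation_fidelity(pts[1:2, ], exact, g), ">= 3")
})
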