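# construction helper: transect with known labels
make_transect <- function(seed = 2, terrain = function(x) 100 + 5 *
                            sin(x / 80),
                          n_canopy = 500, canopy_lo = 8, canopy_hi = 15,
                          n_noise = 0, length_m = 1000) {
  with_seed(seed, {
    at_g <- seq(0.5, length_m - 0.5, by = 1)
    g_el <- terrain(at_g) + rnorm(length(at_g), sd = 0.05)
    c_at <- runif(n_canopy, 0, length_m)
    c_el <- terrain(c_at) + runif(n_canopy, canopy_lo, canopy_hi)
    n_at <- runif(n_noise, 0, length_m)
    n_el <- runif(n_noise, min(g_el) - 25, max(c_el) + 25)
    photon_cloud(c(at_g, c_at, n_at), c(g_el, c_el, n_el),
                 c(rep("ground", length(at_g)), rep("canopy", n_canopy),
                   rep("noise", n_noise)))
  })
}

test_that("denoising honors its quantile contract", {
  cl <- make_transect(n_noise = 0)
  dn <- denoise_photons(cl, 15, 3, density_quantile = 0)
  expect_equal(dn$along_track, cl$along_track)
  expect_equal(dn$elevation, cl$elevation)

  one <- photon_cloud(5, 100)
  expect_equal(nrow(denoise_photons(one, 10, 2, 0.5)), 1)

  # dense signal band + sparse noise (10x density ratio), quantile tuned
  # to the noise fraction: >= 90% of noise removed, >= 95% signal kept
  with_seed(9, {
    n_sig <- 2000; n_noise <- 1000
    cl2 <- photon_cloud(
      c(runif(n_sig, 0, 1000), runif(n_noise, 0, 1000)),
      c(100 + runif(n_sig, 0, 5), runif(n_noise, 60, 140)),
      c(rep("canopy", n_sig), rep("noise", n_noise)))
    dn2 <- denoise_photons(cl2, 15, 3, n_noise / (n_sig + n_noise))
    expect_gte(1 - sum(dn2$true_label == "noise") / n_noise, 0.9)
    expect_gte(sum(dn2$true_label == "canopy") / n_sig, 0.95)
  })
})

test_that("ground seeds are window minima and never canopy", {
  cl <- make_transect(seed = 4, terrain = function(x) 100 + 0 * x)
  s <- find_ground_seeds(cl, 200)
  expect_lte(length(s), ceiling(1000 / 200))
  expect_true(all(cl$true_label[s] == "ground"))

  # 600 m transect, window 200 -> at most 3 seeds
  short <- photon_cloud(seq(1, 599, by = 2), rnorm(300, 100, 0.1))
  expect_lte(length(find_ground_seeds(short, 200)), 3)

  # monotone ramp, ground only: seed = first photon of each window
  ramp <- photon_cloud(seq(0.5, 599.5, 1), 100 + 0.05 * seq(0.5, 599.5, 1))
  expect_equal(find_ground_seeds(ramp, 200), c(1L, 201L, 401L))
})

test_that("PTD classification recovers construction labels", {
  cl <- make_transect(seed = 2)
  pc <- classify_ptd(cl, ptd_params())
  tp <- sum(pc$pred_label == "ground" & pc$true_label == "ground")
  expect_gte(tp / sum(pc$true_label == "ground"), 0.9)
  expect_gte(tp / sum(pc$pred_label == "ground"), 0.9)

  # all photons on a line -> all ground
  lin <- photon_cloud(seq(1, 500, 1), 100 + 0.01 * seq(1, 500, 1))
  pl <- classify_ptd(lin, ptd_params())
  expect_true(all(pl$pred_label == "ground"))

  # idempotence: re-classification changes no label
  pc2 <- classify_ptd(pc, ptd_params())
  expect_identical(pc$pred_label, pc2$pred_label)

  # spline bounded by the photon elevations
  spl <- attr(pc, "ground_spline")
  xs <- seq(0, 1000, by = 5)
  expect_true(all(spl(xs) >= min(cl$elevation) - 1e-9 &
                    spl(xs) <= max(cl$elevation) + 1e-9))

  # canopy photons above a flat band produce no canopy-labelled ground
  flat <- make_transect(seed = 6, terrain = function(x) 200 + 0 * x)
  pf <- classify_ptd(flat, ptd_params())
  expect_lt(mean(pf$pred_label == "ground" & pf$true_label == "canopy"),
            0.01)

  expect_error(classify_ptd(photon_cloud(c(1, 2), c(5, 6)), ptd_params()),
               "classification failure")
})

test_that("noise robustness: recall never increases with noise density", {
  recalls <- vapply(c(0, 150, 400), function(nn) {
    cl <- make_transect(seed = 3, n_noise = nn)
    dn <- if (nn > 0) denoise_photons(cl, 15, 3, 0.1) else cl
    pc <- classify_ptd(dn, ptd_params())
    sum(pc$pred_label == "ground" & pc$true_label == "ground") /
      sum(pc$true_label == "ground")
  }, 0)
  expect_true(all(diff(recalls) <= 1e-9))
  expect_gte(recalls[1], 0.9)
})

test_that("footprint metrics per 100 m segment", {
  # flat ground at 100 m with canopy at 110 m
  with_seed(1, {
    at <- seq(0.5, 999.5, 1)
    cl <- photon_cloud(c(at, at), c(rep(100, 1000), rep(110, 1000)),
                       c(rep("ground", 1000), rep("canopy", 1000)))
  })
  pc <- classify_ptd(cl, ptd_params())
  seg <- extract_footprint_metrics(pc, 100)
  expect_equal(nrow(seg), 10)
  expect_equal(seg$h_mean_canopy_abs, rep(10, 10), tolerance = 1e-6)
  expect_equal(seg$h_te_best_fit, rep(100, 10), tolerance = 1e-6)

  # noiseless ramp, slope 0.05: per-segment line fit error < 0.1 m
  ramp <- photon_cloud(seq(0.5, 999.5, 1), 100 + 0.05 * seq(0.5, 999.5, 1))
  pr <- classify_ptd(ramp, ptd_params())
  sr <- extract_footprint_metrics(pr, 100)
  expect_true(all(abs(sr$h_te_best_fit -
                        (100 + 0.05 * sr$center_m)) < 0.1))

  # segment without ground photons -> flagged missing
  sparse <- photon_cloud(c(seq(0.5, 99.5, 1), seq(400.5, 499.5, 1)),
                         rep(100, 200))
  ps <- classify_ptd(sparse, ptd_params())
  ss <- extract_footprint_metrics(ps, 100)
  expect_true(is.na(ss$h_te_best_fit[ss$n_ground == 0][1]))
})
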