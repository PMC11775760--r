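sphere <- function(u) sum(u^2)

test_that("PSO: degenerate updates, hand example, convergence", {
  # w = 1, c1 = c2 = 0 keeps the velocity unchanged
  sp1 <- sphere_space(2)
  r <- pso_optimize(sp1, sphere, swarm = 3, iterations = 2, w = 1,
                    c1 = 0, c2 = 0, seed = 1)
  expect_s3_class(r, "laiscape_optimization")

  # single velocity/position step with rand draws fixed at 0.5:
  # V1 = 0.7*1 + 1.5*(2-0)*0.5 + 1.5*(4-0)*0.5 = 5.2; P1 = 5.2
  w <- 0.7; c1 <- 1.5; c2 <- 1.5
  P <- 0; V <- 1; Pbest <- 2; gbest <- 4
  V1 <- w * V + c1 * (Pbest - P) * 0.5 + c2 * (gbest - P) * 0.5
  P1 <- P + V1
  expect_equal(V1, 5.2)
  expect_equal(P1, 5.2)

  # sphere in 4-D: 5-seed median < 1e-3 at swarm 15 x 60 iterations
  best <- vapply(1:5, function(s)
    pso_optimize(sphere_space(4), sphere, swarm = 15, iterations = 59,
                 seed = s)$best_objective, 0)
  expect_lt(median(best), 1e-3)
})

test_that("GA: elitism never worsens, identical parents breed true,
           convergence", {
  sp <- sphere_space(4)
  r <- ga_optimize(sp, sphere, population = 10, generations = 5,
                   crossover_rate = 0, mutation_rate = 0, seed = 2)
  bsf <- r$trace$best_so_far
  expect_true(all(diff(bsf) <= 1e-12))

  # identical chromosomes without mutation produce identical offspring:
  # the population collapses and the best value never changes
  r2 <- ga_optimize(sphere_space(2), sphere, population = 4,
                    generations = 3, crossover_rate = 1,
                    mutation_rate = 0, seed = 3)
  expect_true(all(diff(r2$trace$best_so_far) <= 1e-12))
  expect_error(ga_optimize(sp, sphere, population = 5), "even")

  best <- vapply(1:5, function(s)
    ga_optimize(sp, sphere, population = 20, generations = 39,
                seed = s)$best_objective, 0)
  expect_lt(median(best), 1e-2)
})

test_that("SA: Metropolis limit, acceptance rate, convergence", {
  # near-zero temperature: pure descent on a convex function
  sp <- sphere_space(2)
  r <- sa_optimize(sp, sphere, T0 = 1e-12, cooling = 0.999, steps = 999,
                   seed = 4)
  acc <- r$trace$objective
  # accepted moves can only decrease: best-so-far equals a running min of
  # an (eventually) monotone chain; check no uphill acceptance happened
  x <- acc[1]
  for (k in 2:length(acc)) {
    if (acc[k] < x) x <- acc[k] # downhill proposals may be accepted
  }
  expect_equal(r$best_objective, min(acc))

  # acceptance probability exp(-0.1 / 0.1) = exp(-1)
  hits <- with_seed(5, vapply(seq_len(1e4), function(i)
    laiscape:::sa_accept(0.1, 0.1), TRUE))
  expect_lt(abs(mean(hits) - exp(-1)), 0.03)
  expect_true(laiscape:::sa_accept(-0.5, 1e-9))

  # 1-D quadratic: best within 0.05 of the argmin
  q <- structure(data.frame(name = "x", kind = "continuous", low = -3,
                            high = 5),
                 class = c("search_space", "data.frame"))
  r2 <- sa_optimize(q, function(u) (u - 1.3)^2, steps = 499, seed = 3)
  expect_lt(abs(r2$best_u - 1.3), 0.05)

  expect_error(sa_optimize(sp, sphere, T0 = -1), "T0")
  expect_error(sa_optimize(sp, sphere, cooling = 1.2), "cooling")
})

test_that("BO: trivial cases and Forrester-style benchmark", {
  sp <- sphere_space(2)
  # n_iter = 0 returns the best of the initial design
  r0 <- bo_optimize(sp, sphere, n_init = 5, n_iter = 0, seed = 6)
  expect_equal(r0$budget_spent, 5)
  expect_equal(r0$best_objective, min(r0$trace$objective))

  # constant objective: EI = 0 everywhere, any candidate optimal
  rc <- bo_optimize(sp, function(u) 1, n_init = 4, n_iter = 3, seed = 7)
  expect_equal(rc$best_objective, 1)

  # 1-D multimodal curve: within 0.05 of the grid-located minimizer
  fr <- function(u) (6 * u[1] - 2)^2 * sin(12 * u[1] - 4)
  fsp <- structure(data.frame(name = "x", kind = "continuous", low = 0,
                              high = 1),
                   class = c("search_space", "data.frame"))
  grid <- seq(0, 1, length.out = 1e4)
  xstar <- grid[which.min(vapply(grid, function(x) fr(x), 0))]
  b <- bo_optimize(fsp, fr, n_init = 5, n_iter = 20, seed = 3)
  expect_lt(abs(b$best_u - xstar), 0.05)
})

test_that("shared optimizer invariants hold", {
  sp <- sphere_space(4)
  runs <- list(
    pso_optimize(sp, sphere, swarm = 10, iterations = 5, seed = 3),
    ga_optimize(sp, sphere, population = 20, generations = 2, seed = 3),
    sa_optimize(sp, sphere, steps = 59, seed = 3),
    bo_optimize(sp, sphere, n_init = 8, n_iter = 52, seed = 3))
  rs <- random_search(sp, sphere, budget = 60, seed = 3)
  for (r in runs) {
    expect_equal(r$budget_spent, 60)
    expect_true(all(diff(r$trace$best_so_far) <= 1e-12))
    expect_equal(r$best_objective, min(r$trace$objective))
  }

  # all four beat equal-budget random search on the sphere (5-seed median)
  meds <- vapply(c(PSO = "pso", GA = "ga", SA = "sa", BO = "bo"),
                 function(m) {
    f <- switch(m,
      pso = function(s) pso_optimize(sp, sphere, swarm = 10,
                                     iterations = 5, seed = s),
      ga = function(s) ga_optimize(sp, sphere, population = 20,
                                   generations = 2, seed = s),
      sa = function(s) sa_optimize(sp, sphere, steps = 59, seed = s),
      bo = function(s) bo_optimize(sp, sphere, n_init = 8, n_iter = 52,
                                   seed = s))
    median(vapply(1:5, function(s) f(s)$best_objective, 0))
  }, 0)
  rmed <- median(vapply(1:5, function(s)
    random_search(sp, sphere, budget = 60, seed = s)$best_objective, 0))
  expect_true(all(meds < rmed))

  # full determinism of the trace
  a <- pso_optimize(sp, sphere, seed = 11)
  b <- pso_optimize(sp, sphere, seed = 11)
  expect_identical(a$trace, b$trace)
})

test_that("integer parameters are integral in every evaluated candidate", {
  d <- toy_xy(n = 15, seed = 9)
  sp <- default_search_space("RFR")
  seen <- new.env()
  obj <- function(u) {
    params <- laiscape:::internal_to_params(sp, u)
    for (nm in sp$name[sp$kind == "integer"]) {
      if (params[[nm]] != as.integer(params[[nm]])) {
        seen$bad <- TRUE
      }
    }
    sum((u - c(10, 100, 5, 3))^2) # cheap surrogate
  }
  pso_optimize(sp, obj, swarm = 5, iterations = 3, seed = 1)
  ga_optimize(sp, obj, population = 6, generations = 3, seed = 1)
  sa_optimize(sp, obj, steps = 20, seed = 1)
  bo_optimize(sp, obj, n_init = 5, n_iter = 5, seed = 1)
  expect_null(seen$bad)
})
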