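#' @name optimizers
#' @title Metaheuristic hyperparameter optimizers
#'
#' @description Four derivative-free minimizers over a [default_search_space()]:
#' particle swarm ([pso_optimize()]), a real-coded genetic algorithm
#' ([ga_optimize()]), simulated annealing ([sa_optimize()]) and Gaussian-
#' process Bayesian optimization ([bo_optimize()]), plus a pure random
#' search baseline ([random_search()]).  All work on a continuous internal
#' representation (log10 scale for log parameters, integers rounded at
#' evaluation only), share a common evaluation-budget accounting and return
#' the best evaluated candidate with its trace.  Fixing (space, objective,
#' budget, seed) fixes the trace bit-for-bit.
NULL

# shared bookkeeping: record an evaluation, maintain best-so-far
new_trace <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$best_obj <- Inf
  env$best_u <- NULL
  env
}

record_eval <- function(tr, u, val) {
  if (val < tr$best_obj) {
    tr$best_obj <- val
    tr$best_u <- u
  }
  tr$rows[[length(tr$rows) + 1L]] <-
    c(val, tr$best_obj, u)
  invisible(tr)
}

trace_df <- function(tr, space) {
  m <- do.call(rbind, tr$rows)
  df <- as.data.frame(m)
  names(df) <- c("objective", "best_so_far", space$name)
  df$evaluation <- seq_len(nrow(df))
  df
}

finish_result <- function(tr, space, seed, method) {
  params <- internal_to_params(space, tr$best_u)
  structure(list(method = method, best_params = params,
                 best_objective = tr$best_obj, best_u = tr$best_u,
                 trace = trace_df(tr, space), seed = seed,
                 budget_spent = length(tr$rows)),
            class = "laiscape_optimization")
}

#' @export
print.laiscape_optimization <- function(x, ...) {
  cat(sprintf("%s: best objective %.6g after %d evaluations\n  %s\n",
              x$method, x$best_objective, x$budget_spent,
              paste(names(x$best_params),
                    vapply(x$best_params, format, ""),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Particle swarm optimization
#'
#' Velocity update `V' = w V + c1 (Pbest - P) r1 + c2 (gbest - P) r2` with
#' fresh independent `r ~ U(0, 1)` draws per term and dimension, then
#' `P' = P + V'`; positions are clamped to the bounds.
#'
#' @param space a `search_space`.
#' @param objective function of the internal vector (see
#'   [make_tuning_objective()]).
#' @param swarm particle count (>= 2).
#' @param iterations update sweeps; total budget is
#'   `swarm * (iterations + 1)`.
#' @param w,c1,c2 inertia and learning factors.
#' @param seed integer seed.
#' @param init optional internal-scale start candidate (warm start); the
#'   tuning pipeline seeds every optimizer with the library-default
#'   configuration so tuning can only match or improve on it.
#' @return a `laiscape_optimization`.
#' @export
pso_optimize <- function(space, objective, swarm = 10, iterations = 5,
                         w = 0.7, c1 = 1.5, c2 = 1.5, seed = 1,
                         init = NULL) {
  if (swarm < 2) stopf("swarm must be >= 2")
  si <- space_to_internal(space)
  d <- length(si$low)
  with_seed(derive_seed(seed, 11L), {
    tr <- new_trace()
    P <- t(replicate(swarm, runif(d, si$low, si$high)))
    if (!is.null(init)) P[1, ] <- pmin(pmax(init, si$low), si$high)
    V <- t(replicate(swarm, runif(d, -(si$high - si$low) / 4,
                                  (si$high - si$low) / 4)))
    pbest <- P
    pbest_val <- apply(P, 1, function(u) {
      val <- objective(u)
      record_eval(tr, u, val)
      val
    })
    g <- which.min(pbest_val)
    gbest <- pbest[g, ]
    gbest_val <- pbest_val[g]
    for (it in seq_len(iterations)) {
      for (i in seq_len(swarm)) {
        r1 <- runif(d)
        r2 <- runif(d)
        V[i, ] <- w * V[i, ] + c1 * (pbest[i, ] - P[i, ]) * r1 +
          c2 * (gbest - P[i, ]) * r2
        P[i, ] <- pmin(pmax(P[i, ] + V[i, ], si$low), si$high)
        val <- objective(P[i, ])
        record_eval(tr, P[i, ], val)
        if (val < pbest_val[i]) {
          pbest[i, ] <- P[i, ]
          pbest_val[i] <- val
          if (val < gbest_val) {
            gbest <- P[i, ]
            gbest_val <- val
          }
        }
      }
    }
    finish_result(tr, space, seed, "PSO")
  })
}

#' Genetic-algorithm optimization
#'
#' Real-coded chromosomes, tournament selection (size 2), blend (BLX-alpha
#' style uniform) crossover, Gaussian mutation scaled to 10% of each bound
#' width, elitism of one.
#'
#' @param space,objective,seed as in [pso_optimize()].
#' @param population even population size.
#' @param generations generations after the initial one; total budget
#'   `population * (generations + 1)`.
#' @param crossover_rate,mutation_rate per-pair / per-gene probabilities.
#' @return a `laiscape_optimization`.
#' @export
ga_optimize <- function(space, objective, population = 20, generations = 2,
                        crossover_rate = 0.8, mutation_rate = 0.1,
                        seed = 1, init = NULL) {
  if (population %% 2 != 0) stopf("population must be even")
  si <- space_to_internal(space)
  d <- length(si$low)
  width <- si$high - si$low
  with_seed(derive_seed(seed, 12L), {
    tr <- new_trace()
    pop <- t(replicate(population, runif(d, si$low, si$high)))
    if (!is.null(init)) pop[1, ] <- pmin(pmax(init, si$low), si$high)
    fit <- apply(pop, 1, function(u) {
      val <- objective(u)
      record_eval(tr, u, val)
      val
    })
    for (gen in seq_len(generations)) {
      elite_i <- which.min(fit)
      elite <- pop[elite_i, ]
      elite_fit <- fit[elite_i]
      tournament <- function() {
        ij <- sample.int(population, 2)
        if (fit[ij[1]] <= fit[ij[2]]) pop[ij[1], ] else pop[ij[2], ]
      }
      children <- matrix(0, population, d)
      for (k in seq_len(population / 2)) {
        p1 <- tournament()
        p2 <- tournament()
        if (runif(1) < crossover_rate) {
          a <- runif(d)
          c1v <- a * p1 + (1 - a) * p2
          c2v <- (1 - a) * p1 + a * p2
        } else {
          c1v <- p1
          c2v <- p2
        }
        children[2 * k - 1, ] <- c1v
        children[2 * k, ] <- c2v
      }
      mut <- matrix(runif(population * d) < mutation_rate, population, d)
      if (any(mut)) {
        noise <- matrix(rnorm(population * d), population, d) *
          rep(0.1 * width, each = population)
        children[mut] <- children[mut] + noise[mut]
      }
      children <- pmin(pmax(children,
                            rep(si$low, each = population)),
                       rep(si$high, each = population))
      children[1, ] <- elite # elitism of 1
      pop <- children
      fit <- apply(pop, 1, function(u) {
        val <- objective(u)
        record_eval(tr, u, val)
        val
      })
      fit[1] <- elite_fit
    }
    finish_result(tr, space, seed, "GA")
  })
}

#' Simulated-annealing optimization
#'
#' Gaussian proposals (scale 10% of each bound width, shrinking with
#' temperature), Metropolis acceptance `exp(-df / T)`, geometric cooling
#' per step; returns the best candidate ever evaluated.
#'
#' @param space,objective,seed as in [pso_optimize()].
#' @param T0 initial temperature (> 0); default `NULL` sets it to the
#'   initial objective magnitude.
#' @param cooling geometric cooling factor in (0, 1).
#' @param steps proposal count; budget is `steps + 1`.
#' @return a `laiscape_optimization`.
#' @export
sa_optimize <- function(space, objective, T0 = NULL, cooling = 0.95,
                        steps = 59, seed = 1, init = NULL) {
  if (!is.null(T0) && T0 <= 0) stopf("T0 must be positive")
  if (cooling <= 0 || cooling >= 1) stopf("cooling must be in (0, 1)")
  si <- space_to_internal(space)
  d <- length(si$low)
  width <- si$high - si$low
  with_seed(derive_seed(seed, 13L), {
    tr <- new_trace()
    x <- if (is.null(init)) runif(d, si$low, si$high) else
      pmin(pmax(init, si$low), si$high)
    fx <- objective(x)
    record_eval(tr, x, fx)
    temp <- if (is.null(T0)) max(abs(fx), 1e-3) else T0
    for (s in seq_len(steps)) {
      scale <- 0.1 * width * max(temp / max(temp, 1), 0.1)
      prop <- pmin(pmax(x + rnorm(d) * scale, si$low), si$high)
      fp <- objective(prop)
      record_eval(tr, prop, fp)
      if (sa_accept(fp - fx, temp)) {
        x <- prop
        fx <- fp
      }
      temp <- temp * cooling
    }
    finish_result(tr, space, seed, "SA")
  })
}

#' Gaussian-process Bayesian optimization
#'
#' Latin-hypercube initial design; zero-mean GP surrogate with Matern-5/2
#' kernel on unit-scaled inputs (lengthscale and noise chosen by marginal
#' likelihood over a small grid); expected-improvement acquisition
#' maximized by 1024 random samples plus a local Nelder-Mead polish.  GP
#' failures fall back to a random proposal for that iteration.
#'
#' @param space,objective,seed as in [pso_optimize()].
#' @param n_init initial design size (>= 3).
#' @param n_iter sequential proposals; budget `n_init + n_iter`.
#' @return a `laiscape_optimization`.
#' @export
bo_optimize <- function(space, objective, n_init = 8, n_iter = 52,
                        seed = 1, init = NULL) {
  if (n_init < 3) stopf("n_init must be >= 3")
  si <- space_to_internal(space)
  d <- length(si$low)
  width <- si$high - si$low
  with_seed(derive_seed(seed, 14L), {
    tr <- new_trace()
    # Latin hypercube in unit space
    U <- sapply(seq_len(d), function(j) {
      (sample.int(n_init) - runif(n_init)) / n_init
    })
    U <- matrix(U, n_init, d)
    if (!is.null(init)) {
      U[1, ] <- (pmin(pmax(init, si$low), si$high) - si$low) / width
    }
    X <- sweep(sweep(U, 2, width, `*`), 2, si$low, `+`)
    y <- apply(X, 1, function(u) {
      val <- objective(u)
      record_eval(tr, u, val)
      val
    })
    Xu <- U
    for (it in seq_len(n_iter)) {
      gp <- tryCatch(gp_fit(Xu, y), error = function(e) NULL)
      if (is.null(gp)) {
        u_new <- runif(d)
        log_msg("bo_optimize: GP fit failed, random proposal")
      } else {
        cand <- matrix(runif(1024 * d), 1024, d)
        ei <- gp_expected_improvement(gp, cand, min(y))
        u0 <- cand[which.max(ei), ]
        polish <- tryCatch(
          optim(u0, function(u) {
            if (any(u < 0 | u > 1)) return(0)
            -gp_expected_improvement(gp, matrix(u, 1), min(y))
          }, method = "Nelder-Mead",
          control = list(maxit = 50, warn.1d.NelderMead = FALSE)),
          error = function(e) NULL)
        u_new <- if (!is.null(polish) &&
                     -polish$value >= max(ei)) polish$par else u0
        u_new <- pmin(pmax(u_new, 0), 1)
      }
      x_new <- si$low + u_new * width
      val <- objective(x_new)
      record_eval(tr, x_new, val)
      Xu <- rbind(Xu, u_new)
      y <- c(y, val)
    }
    finish_result(tr, space, seed, "BO")
  })
}

#' Random-search baseline
#'
#' Uniform sampling over the space with the same budget accounting as the
#' metaheuristics; the yardstick the four optimizers must beat.
#'
#' @param space,objective,seed as in [pso_optimize()].
#' @param budget number of evaluations.
#' @return a `laiscape_optimization`.
#' @export
random_search <- function(space, objective, budget = 60, seed = 1) {
  si <- space_to_internal(space)
  d <- length(si$low)
  with_seed(derive_seed(seed, 15L), {
    tr <- new_trace()
    for (b in seq_len(budget)) {
      u <- runif(d, si$low, si$high)
      record_eval(tr, u, objective(u))
    }
    finish_result(tr, space, seed, "random")
  })
}

# Metropolis acceptance rule (factored out for direct testing)
sa_accept <- function(df, temp) {
  df <= 0 || runif(1) < exp(-df / temp)
}

# ---- minimal Gaussian process machinery for BO --------------------------

matern52 <- function(r) {
  s <- sqrt(5) * r
  (1 + s + s^2 / 3) * exp(-s)
}

gp_fit <- function(X, y, lengthscales = c(0.1, 0.2, 0.4, 0.8, 1.6),
                   noises = c(1e-8, 1e-4, 1e-2)) {
  n <- nrow(X)
  mu <- mean(y)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  D <- as.matrix(dist(X))
  best <- NULL
  for (l in lengthscales) {
    K0 <- matern52(D / l)
    for (nz in noises) {
      K <- K0 + diag(nz, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      # log marginal likelihood up to constants
      ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
      if (is.null(best) || ll > best$ll) {
        best <- list(ll = ll, l = l, nz = nz, chol = ch, alpha = alpha)
      }
    }
  }
  if (is.null(best)) stopf("GP fit failed")
  list(X = X, mu = mu, sdy = sdy, l = best$l, nz = best$nz,
       chol = best$chol, alpha = best$alpha)
}

gp_predict <- function(gp, Xnew) {
  # cross-distances
  nn <- nrow(Xnew)
  n <- nrow(gp$X)
  D <- sqrt(pmax(outer(rowSums(Xnew^2), rowSums(gp$X^2), `+`) -
                   2 * Xnew %*% t(gp$X), 0))
  Ks <- matern52(D / gp$l)
  mean_s <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  var_s <- pmax(1 + gp$nz - colSums(v^2), 1e-12)
  list(mean = mean_s * gp$sdy + gp$mu, sd = sqrt(var_s) * gp$sdy)
}

gp_expected_improvement <- function(gp, Xnew, f_best) {
  pr <- gp_predict(gp, Xnew)
  imp <- f_best - pr$mean
  z <- imp / pr$sd
  ei <- imp * pnorm(z) + pr$sd * dnorm(z)
  ei[pr$sd < 1e-12] <- 0
  ei
}
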