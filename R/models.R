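#' Hyperparameter search space
#'
#' Tabulates, per parameter, its kind (integer / continuous /
#' log-continuous) and bounds.  Defaults cover the tree depth, tree count
#' and node-size controls of the forest and boosting families, the boosting
#' learning rate, and the RBF cost/kernel parameters of SVR.
#'
#' @param kind model family: "RFR", "GBRT" or "SVR".
#' @return a `search_space` data frame with columns `name`, `kind`, `low`,
#'   `high`.
#' @export
default_search_space <- function(kind = c("RFR", "GBRT", "SVR")) {
  kind <- match.arg(kind)
  sp <- switch(kind,
    RFR = data.frame(
      name = c("max_depth", "n_estimators", "min_samples_split",
               "min_samples_leaf"),
      kind = c("integer", "integer", "integer", "integer"),
      low = c(2, 50, 2, 1), high = c(20, 800, 20, 10)),
    GBRT = data.frame(
      name = c("max_depth", "n_estimators", "min_samples_split",
               "min_samples_leaf", "learning_rate"),
      kind = c("integer", "integer", "integer", "integer",
               "log-continuous"),
      low = c(2, 50, 2, 1, 0.01), high = c(20, 800, 20, 10, 0.3)),
    SVR = data.frame(
      name = c("cost_parameter", "kernel_coefficient"),
      kind = c("log-continuous", "log-continuous"),
      low = c(1e-2, 1e-4), high = c(1e3, 10))
  )
  if (any(!(sp$low < sp$high)) || any(!is.finite(c(sp$low, sp$high)))) {
    stopf("invalid bounds")
  }
  attr(sp, "model_kind") <- kind
  class(sp) <- c("search_space", "data.frame")
  sp
}

# internal representation: optimizers work on a continuous vector u (log10
# scale for log-continuous parameters); integers are rounded at evaluation
# only
space_to_internal <- function(space) {
  low <- ifelse(space$kind == "log-continuous", log10(space$low), space$low)
  high <- ifelse(space$kind == "log-continuous", log10(space$high),
                 space$high)
  list(low = low, high = high, names = space$name, kinds = space$kind)
}

internal_to_params <- function(space, u) {
  vals <- as.list(ifelse(space$kind == "log-continuous", 10^u, u))
  names(vals) <- space$name
  for (i in seq_len(nrow(space))) {
    if (space$kind[i] == "integer") vals[[i]] <- as.integer(round(vals[[i]]))
  }
  vals
}

# canonical regression-forest default: a third of the features per split
rfr_mtry <- function(p) max(1L, p %/% 3L)

# internal-scale vector for a named parameter list (warm starts)
params_to_internal <- function(space, params) {
  vapply(seq_len(nrow(space)), function(i) {
    v <- params[[space$name[i]]]
    if (is.null(v) || is.na(v)) v <- (space$low[i] + space$high[i]) / 2
    if (space$kind[i] == "log-continuous") log10(v) else as.numeric(v)
  }, 0)
}

default_params <- function(kind) {
  switch(kind,
    RFR = list(max_depth = 20L, n_estimators = 100L,
               min_samples_split = 2L, min_samples_leaf = 1L),
    GBRT = list(max_depth = 3L, n_estimators = 100L,
                min_samples_split = 2L, min_samples_leaf = 1L,
                learning_rate = 0.1),
    SVR = list(cost_parameter = 1, kernel_coefficient = NA_real_))
}

#' Train a regressor
#'
#' @param kind "RFR" (bagged CART forest), "GBRT" (gradient-boosted trees,
#'   squared loss) or "SVR" (epsilon-SVR, RBF kernel; inputs standardized
#'   internally).
#' @param params named list of hyperparameters (missing entries take the
#'   family defaults; `kernel_coefficient` defaults to `1/ncol(X)`).
#' @param X numeric matrix (or data frame) of predictors.
#' @param y numeric response.
#' @param seed integer seed (forest bootstrap; other families are
#'   deterministic).
#' @return a `laiscape_model`.
#' @export
train_model <- function(kind, params = list(), X, y, seed = 1) {
  kind <- match.arg(kind, c("RFR", "GBRT", "SVR"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stopf("X and y must be finite")
  }
  p <- utils::modifyList(default_params(kind), params)
  fit <- switch(kind,
    RFR = list(trees = cpp_rfr_fit(X, y, as.integer(p$n_estimators),
                                   as.integer(p$max_depth),
                                   as.integer(p$min_samples_split),
                                   as.integer(p$min_samples_leaf),
                                   rfr_mtry(ncol(X)),
                                   as.double(derive_seed(seed, 0L)))),
    GBRT = cpp_gbrt_fit(X, y, as.integer(p$n_estimators),
                        p$learning_rate, as.integer(p$max_depth),
                        as.integer(p$min_samples_split),
                        as.integer(p$min_samples_leaf)),
    SVR = {
      if (is.na(p$kernel_coefficient)) p$kernel_coefficient <- 1 / ncol(X)
      ctr <- colMeans(X)
      scl <- apply(X, 2, sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, ctr, scl)
      ymu <- mean(y)
      ysd <- if (sd(y) > 0) sd(y) else 1
      ys <- (y - ymu) / ysd
      sv <- cpp_svr_fit(Xs, ys, p$cost_parameter, p$kernel_coefficient,
                        0.1, 1e-3, 20000L)
      list(beta = sv$beta, b = sv$b, Xs = Xs, ctr = ctr, scl = scl,
           ymu = ymu, ysd = ysd)
    })
  structure(list(kind = kind, params = p, fit = fit,
                 feature_names = colnames(X), seed = seed),
            class = "laiscape_model")
}

#' Predict from a trained regressor
#' @param object a `laiscape_model`.
#' @param newdata matrix or data frame of predictors (column order must
#'   match training).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.laiscape_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    stopf("feature column mismatch: expected [%s]",
          paste(object$feature_names, collapse = ", "))
  }
  switch(object$kind,
    RFR = as.numeric(cpp_forest_predict(object$fit$trees, X)),
    GBRT = as.numeric(cpp_gbrt_predict(object$fit$init, object$fit$trees,
                                       object$fit$learning_rate, X)),
    SVR = {
      f <- object$fit
      Xs <- scale(X, f$ctr, f$scl)
      as.numeric(cpp_svr_predict(f$Xs, f$beta, f$b,
                                 object$params$kernel_coefficient, Xs)) *
        f$ysd + f$ymu
    })
}

#' @export
print.laiscape_model <- function(x, ...) {
  cat(sprintf("laiscape_model: %s (%s)\n", x$kind,
              paste(names(x$params), unlist(lapply(x$params, format)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Leave-one-out cross-validated predictions
#'
#' Refits the model n times, each time holding one observation out, with a
#' fixed per-fold seed derived from `seed` so results are reproducible.
#'
#' @param kind,params,X,y,seed as in [train_model()].
#' @return numeric vector of out-of-fold predictions.
#' @export
loocv_predictions <- function(kind, params, X, y, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 3) stopf("need n >= 3 for LOOCV")
  p <- utils::modifyList(default_params(kind), params)
  # tree families go through flat C++ fold drivers (bit-identical to the
  # literal train/predict loop, but without per-tree R allocations)
  if (kind == "RFR") {
    seeds <- vapply(seq_len(n), function(i)
      as.double(derive_seed(derive_seed(seed, i), 0L)), 0)
    return(as.numeric(cpp_rfr_loocv(X, y, as.integer(p$n_estimators),
                                    as.integer(p$max_depth),
                                    as.integer(p$min_samples_split),
                                    as.integer(p$min_samples_leaf),
                                    rfr_mtry(ncol(X)), seeds)))
  }
  if (kind == "GBRT") {
    return(as.numeric(cpp_gbrt_loocv(X, y, as.integer(p$n_estimators),
                                     p$learning_rate,
                                     as.integer(p$max_depth),
                                     as.integer(p$min_samples_split),
                                     as.integer(p$min_samples_leaf))))
  }
  vapply(seq_len(n), function(i) {
    m <- train_model(kind, params, X[-i, , drop = FALSE], y[-i],
                     seed = derive_seed(seed, i))
    predict(m, X[i, , drop = FALSE])
  }, 0)
}

#' LOOCV RMSE tuning objective
#'
#' The quantity all four optimizers minimize.  Degenerate hyperparameters
#' (e.g. `min_samples_split` exceeding the fold size) earn a penalty of
#' `10 * sd(y)` instead of a fit.
#'
#' @param kind,params,X,y,seed as in [train_model()].
#' @return LOOCV RMSE (scalar).
#' @export
loocv_objective <- function(kind, params, X, y, seed = 1) {
  n <- nrow(as.matrix(X))
  p <- utils::modifyList(default_params(kind), params)
  if (kind %in% c("RFR", "GBRT")) {
    if (p$min_samples_split > n - 1 || p$min_samples_leaf > (n - 1) / 2 ||
        p$max_depth < 1 || p$n_estimators < 1) {
      log_msg("degenerate params for %s; penalty objective", kind)
      return(10 * sd(y))
    }
  } else if (p$cost_parameter <= 0 ||
             (!is.na(p$kernel_coefficient) && p$kernel_coefficient <= 0)) {
    log_msg("degenerate params for %s; penalty objective", kind)
    return(10 * sd(y))
  }
  pred <- loocv_predictions(kind, params, X, y, seed)
  sqrt(mean((y - pred)^2))
}

#' Build a cached tuning objective over a search space
#'
#' Returns `f(u)` mapping an internal parameter vector to the LOOCV RMSE,
#' memoizing on the effective (rounded) parameters so optimizers revisiting
#' the same integer configuration pay nothing.
#'
#' @param space a `search_space`.
#' @param kind,X,y,seed as in [train_model()].
#' @return function of the internal vector `u`.
#' @export
make_tuning_objective <- function(space, kind, X, y, seed = 1) {
  cache <- new.env(parent = emptyenv())
  function(u) {
    params <- internal_to_params(space, u)
    key <- paste(vapply(params, function(v) format(v, digits = 12), ""),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- loocv_objective(kind, params, X, y, seed)
    cache[[key]] <- val
    val
  }
}
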