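#' Accuracy metrics for LAI estimation
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, `MAE = mean(|y - yhat|)` and the
#' overall estimation accuracy `P1 = (1 - RMSE / mean(y)) * 100` (percent).
#'
#' @param y observed values.
#' @param yhat estimates.
#' @return a `metrics_report` list with `R2`, `RMSE`, `MAE`, `P1_percent`,
#'   `n`, `y_mean` and `flags`.
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) {
    stopf("y and yhat must have equal length >= 2")
  }
  n <- length(y)
  ybar <- mean(y)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - ybar)^2)
  flags <- character(0)
  r2 <- if (sst > 0) 1 - sse / sst else {
    flags <- c(flags, "R2_undefined_constant_y")
    NA_real_
  }
  rmse <- sqrt(sse / n)
  mae <- mean(abs(y - yhat))
  p1 <- if (ybar != 0) (1 - rmse / ybar) * 100 else {
    flags <- c(flags, "P1_undefined_zero_mean")
    NA_real_
  }
  structure(list(R2 = r2, RMSE = rmse, MAE = mae, P1_percent = p1, n = n,
                 y_mean = ybar, flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("R2=%.4f  RMSE=%.4f  MAE=%.4f  P1=%.2f%%  (n=%d)\n",
              x$R2, x$RMSE, x$MAE, x$P1_percent, x$n))
  invisible(x)
}

#' Tune one model family with one optimizer
#'
#' @param kind model family ("RFR"/"GBRT"/"SVR").
#' @param optimizer "none", "BO", "PSO", "GA" or "SA".
#' @param X,y training data.
#' @param budget objective-evaluation budget (default 60); `0` skips
#'   tuning and returns the family defaults.
#' @param seed integer seed.
#' @param space optional `search_space` override.
#' @return list with `params`, `optimization` (NULL when untuned).
#' @export
tune_model <- function(kind, optimizer, X, y, budget = 60, seed = 1,
                       space = NULL) {
  if (optimizer == "none" || budget <= 0) {
    params <- default_params(kind)
    if (kind == "SVR" && is.na(params$kernel_coefficient)) {
      params$kernel_coefficient <- 1 / ncol(as.matrix(X))
    }
    return(list(params = params, optimization = NULL))
  }
  if (is.null(space)) space <- default_search_space(kind)
  obj <- make_tuning_objective(space, kind, X, y, seed = seed)
  defaults <- default_params(kind)
  if (kind == "SVR" && is.na(defaults$kernel_coefficient)) {
    defaults$kernel_coefficient <- 1 / ncol(as.matrix(X))
  }
  u0 <- params_to_internal(space, defaults) # warm start at the defaults
  opt <- switch(optimizer,
    BO = bo_optimize(space, obj, n_init = min(8, budget),
                     n_iter = max(budget - 8, 0), seed = seed, init = u0),
    PSO = pso_optimize(space, obj, swarm = 10,
                       iterations = max(budget %/% 10 - 1, 0), seed = seed,
                       init = u0),
    GA = ga_optimize(space, obj, population = 20,
                     generations = max(budget %/% 20 - 1, 0), seed = seed,
                     init = u0),
    SA = sa_optimize(space, obj, steps = budget - 1, seed = seed,
                     init = u0),
    stopf("unknown optimizer '%s'", optimizer))
  list(params = opt$best_params, optimization = opt)
}

#' Compare model families, optimizers and data sources
#'
#' Builds the full grid {RFR, GBRT, SVR} x {none, BO, PSO, GA, SA} x
#' {atlas_only, multisource} (30 rows when both column sets are given),
#' tuning each optimized combination under the shared evaluation budget and
#' reporting leave-one-out metrics.  Failures are flagged and the run
#' continues.
#'
#' @param features a `feature_table` with an `lai` column.
#' @param atlas_columns predictor names for the footprint-only source.
#' @param multisource_columns predictor names for the fused source.
#' @param budget evaluation budget per tuned combination (default 60).
#' @param seed root seed.
#' @param optimizers optimizer set (default all four plus untuned).
#' @return a `comparison_table` data frame; the LOOCV predictions and tuned
#'   parameters of each row are kept in `attr(, "details")`.
#' @export
run_comparison <- function(features, atlas_columns, multisource_columns,
                           budget = 60, seed = 1,
                           optimizers = c("none", "BO", "PSO", "GA",
                                          "SA")) {
  sources <- list(atlas_only = atlas_columns,
                  multisource = multisource_columns)
  sources <- sources[!vapply(sources, is.null, TRUE)]
  for (s in names(sources)) {
    missing <- setdiff(sources[[s]], names(features))
    if (length(missing)) stopf("source '%s' misses column(s): %s", s,
                               paste(missing, collapse = ", "))
  }
  y <- features$lai
  rows <- list()
  details <- list()
  combo <- 0L
  src_i <- 0L
  for (s in names(sources)) {
    src_i <- src_i + 1L
    X <- as.matrix(features[, sources[[s]], drop = FALSE])
    fam_i <- 0L
    for (kind in c("RFR", "GBRT", "SVR")) {
      fam_i <- fam_i + 1L
      # one evaluation-fold seed per (source, family): budget-0 "tuned"
      # rows then reproduce the untuned rows exactly
      eseed <- derive_seed(seed, 100L + src_i * 10L + fam_i)
      for (optname in optimizers) {
        combo <- combo + 1L
        cseed <- derive_seed(seed, combo)
        res <- tryCatch({
          tuned <- tune_model(kind, optname, X, y, budget = budget,
                              seed = cseed)
          pred <- loocv_predictions(kind, tuned$params, X, y, seed = eseed)
          met <- compute_metrics(y, pred)
          list(tuned = tuned, pred = pred, met = met)
        }, error = function(e) e)
        id <- if (optname == "none") kind else paste(optname, kind,
                                                     sep = "-")
        if (inherits(res, "error")) {
          log_msg("combination %s/%s failed: %s", s, id,
                  conditionMessage(res))
          rows[[length(rows) + 1L]] <- data.frame(
            model = id, family = kind, optimizer = optname, source = s,
            R2 = NA_real_, RMSE = NA_real_, MAE = NA_real_,
            P1_percent = NA_real_, n = length(y), seed = eseed,
            budget = budget, failed = TRUE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            model = id, family = kind, optimizer = optname, source = s,
            R2 = res$met$R2, RMSE = res$met$RMSE, MAE = res$met$MAE,
            P1_percent = res$met$P1_percent, n = length(y), seed = eseed,
            budget = budget, failed = FALSE)
          details[[paste(s, id, sep = "/")]] <-
            list(params = res$tuned$params, predictions = res$pred)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$source, -ifelse(is.na(out$R2), -Inf, out$R2)), ]
  rownames(out) <- NULL
  attr(out, "details") <- details
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write comparison outputs
#'
#' Emits the ranked comparison CSV and a wide radar-style summary (one row
#' per model id, one column per metric and source).
#'
#' @param comparison a `comparison_table`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(comparison, file.path(dir, "comparison.csv"),
            row.names = FALSE)
  wide <- stats::reshape(
    comparison[, c("model", "source", "R2", "RMSE", "MAE", "P1_percent")],
    idvar = "model", timevar = "source", direction = "wide")
  write.csv(wide, file.path(dir, "comparison_radar.csv"), row.names = FALSE)
  invisible(dir)
}

#' Wall-to-wall LAI prediction map
#'
#' Applies a trained model pixelwise to a stack of feature layers.  Layer
#' names must cover the model's training columns; column order is checked,
#' not silently fixed.
#'
#' @param model a `laiscape_model`.
#' @param layers named list of feature matrices (shared geometry).
#' @param columns training column order.
#' @param mask optional logical matrix; `TRUE` pixels are skipped
#'   (`NA` in the output).
#' @return a `lai_map` list: `prediction` matrix and `summary`
#'   (min/max/mean over unmasked pixels).
#' @export
predict_map <- function(model, layers, columns = model$feature_names,
                        mask = NULL) {
  missing <- setdiff(columns, names(layers))
  if (length(missing)) stopf("missing layer(s): %s",
                             paste(missing, collapse = ", "))
  if (!is.null(model$feature_names) &&
      !identical(columns, model$feature_names)) {
    stopf("column order mismatch with the trained model")
  }
  d <- dim(layers[[columns[1]]])
  keep <- if (is.null(mask)) rep(TRUE, prod(d)) else !as.vector(mask)
  X <- vapply(columns, function(cn) as.vector(layers[[cn]]),
              numeric(prod(d)))
  pred <- rep(NA_real_, prod(d))
  ok <- keep & apply(is.finite(X), 1, all)
  Xok <- X[ok, , drop = FALSE]
  colnames(Xok) <- columns
  pred[ok] <- predict(model, Xok)
  pm <- matrix(pred, d[1], d[2])
  structure(list(prediction = pm,
                 summary = list(min = min(pred[ok]), max = max(pred[ok]),
                                mean = mean(pred[ok])),
                 model = model$kind, masked = sum(!keep)),
            class = "lai_map")
}

#' Permutation-importance contribution rates
#'
#' Shuffles each predictor 20 times (seeded), measures the mean increase
#' in prediction MSE on the supplied data, normalizes the non-negative
#' importances to sum to 100%, and aggregates them into
#' footprint/SAR/optical source groups.
#'
#' @param model a trained `laiscape_model`.
#' @param features data frame containing the model columns and `lai`.
#' @param n_shuffles permutations per variable (default 20).
#' @param seed integer seed.
#' @return list with `per_variable` (data frame: variable, contribution
#'   percent, group) and `per_group`.
#' @export
contribution_report <- function(model, features, n_shuffles = 20,
                                seed = 1) {
  cols <- model$feature_names
  X <- as.matrix(features[, cols, drop = FALSE])
  y <- features$lai
  base_mse <- mean((y - predict(model, X))^2)
  imp <- with_seed(derive_seed(seed, 21L), {
    vapply(seq_along(cols), function(j) {
      incr <- vapply(seq_len(n_shuffles), function(s) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        mean((y - predict(model, Xp))^2) - base_mse
      }, 0)
      mean(incr)
    }, 0)
  })
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) imp <- rep(1, length(imp)) # uninformative model
  contrib <- imp / sum(imp) * 100
  group <- ifelse(cols %in% c("h_te_best_fit", "h_te_interp",
                              "h_mean_canopy_abs", "solar_elevation"),
                  "atlas",
                  ifelse(grepl("^(VV|VH)", cols), "sar", "optical"))
  per_var <- data.frame(variable = cols, contribution = contrib,
                        group = group)
  per_var <- per_var[order(-per_var$contribution), ]
  rownames(per_var) <- NULL
  per_group <- stats::aggregate(contribution ~ group, per_var, sum)
  list(per_variable = per_var, per_group = per_group)
}
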