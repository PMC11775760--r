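#' Critical Pearson correlation at a significance level
#'
#' Inverts the two-tailed t test `t = r sqrt((n-2)/(1-r^2))`: the smallest
#' `|r|` significant at `alpha` with `n` observations.
#'
#' @param n sample size.
#' @param alpha two-tailed significance level.
#' @return critical `|r|`.
#' @export
critical_r <- function(n, alpha) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Pearson significance screening of candidate predictors
#'
#' Correlates every predictor with the measured LAI and assigns the
#' smallest significance tier (0.01 / 0.05 / 0.1 / none) whose threshold
#' the two-tailed p-value beats.  Zero-variance or non-finite columns are
#' flagged and assigned tier "none".
#'
#' @param features a `feature_table` with an `lai` column.
#' @param alphas nested significance levels, ascending.
#' @param response response column name (default "lai").
#' @return a `screening_result` data frame: `variable`, `r`, `p`, `tier`,
#'   `selected` (tier != none), `flag`.
#' @export
pearson_screen <- function(features, alphas = c(0.01, 0.05, 0.1),
                           response = "lai") {
  if (!response %in% names(features)) stopf("missing response '%s'",
                                            response)
  y <- features[[response]]
  n <- length(y)
  if (n < 5) stopf("need >= 5 rows")
  preds <- setdiff(names(features), c(response, "plot_id"))
  rows <- lapply(preds, function(v) {
    x <- features[[v]]
    flag <- NA_character_
    if (!is.numeric(x) || any(!is.finite(x))) {
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        tier = "none", selected = FALSE,
                        flag = "non_finite"))
    }
    if (sd(x) == 0) {
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        tier = "none", selected = FALSE,
                        flag = "zero_variance"))
    }
    r <- cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tt), df = n - 2)
    }
    tier <- "none"
    for (a in sort(alphas)) {
      if (p < a) {
        tier <- format(a, trim = TRUE)
        break
      }
    }
    data.frame(variable = v, r = r, p = p, tier = tier,
               selected = tier != "none", flag = flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- n
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Reduce the screened set to modeling factors
#'
#' Default policy emulates the 4 + 2 + 2 structure used downstream: all
#' tiered footprint (ATLAS-style) variables, the two strongest tiered SAR
#' texture/backscatter variables and the two strongest tiered optical
#' indices after dropping exact formula-duplicates.  An explicit-list
#' policy passes a verbatim selection through.
#'
#' @param result a `screening_result`.
#' @param features the feature table screened (needed for duplicate
#'   detection; optional).
#' @param policy "group_quota" (default) or "explicit".
#' @param explicit character vector of variable names for the explicit
#'   policy.
#' @param atlas_vars names of the footprint-attribute group.
#' @param sar_quota,optical_quota group quotas under the default policy.
#' @return character vector of selected predictor names.
#' @export
select_modeling_factors <- function(result, features = NULL,
                                    policy = c("group_quota", "explicit"),
                                    explicit = NULL,
                                    atlas_vars = c("h_te_best_fit",
                                                   "h_te_interp",
                                                   "h_mean_canopy_abs",
                                                   "solar_elevation"),
                                    sar_quota = 2, optical_quota = 2) {
  policy <- match.arg(policy)
  if (policy == "explicit") {
    if (is.null(explicit)) stopf("explicit policy needs a name list")
    missing <- setdiff(explicit, result$variable)
    if (length(missing)) stopf("unknown variable(s): %s",
                               paste(missing, collapse = ", "))
    return(explicit)
  }
  tiered <- result[result$selected, , drop = FALSE]
  # drop exact duplicate columns (e.g. RDVI == NDVI), keeping the first
  if (!is.null(features)) {
    keep <- character(0)
    for (v in tiered$variable) {
      dup <- FALSE
      for (k in keep) {
        if (isTRUE(all.equal(features[[v]], features[[k]],
                             tolerance = 0))) {
          dup <- TRUE
          break
        }
      }
      if (!dup) keep <- c(keep, v)
    }
    tiered <- tiered[tiered$variable %in% keep, , drop = FALSE]
  }
  is_atlas <- tiered$variable %in% atlas_vars
  is_sar <- grepl("^(VV|VH)", tiered$variable)
  is_opt <- !is_atlas & !is_sar
  pick_top <- function(df, k) {
    df <- df[order(-abs(df$r)), , drop = FALSE]
    head(df$variable, k)
  }
  sel <- character(0)
  groups <- list(atlas = tiered[is_atlas, ], sar = tiered[is_sar, ],
                 optical = tiered[is_opt, ])
  quotas <- list(atlas = Inf, sar = sar_quota, optical = optical_quota)
  for (g in names(groups)) {
    if (!nrow(groups[[g]])) {
      warning(sprintf("no tiered variable in group '%s'; group omitted", g))
      next
    }
    sel <- c(sel, pick_top(groups[[g]], quotas[[g]]))
  }
  sel
}

#' Write the screening report and correlation matrix
#'
#' @param result a `screening_result`.
#' @param features the feature table (for the correlation matrix).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screening_report <- function(result, features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result, file.path(dir, "screening.csv"), row.names = FALSE)
  num <- features[vapply(features, is.numeric, TRUE)]
  write.csv(round(cor(num), 6), file.path(dir, "correlation_matrix.csv"))
  invisible(dir)
}
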