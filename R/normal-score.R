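#' Normal-score transform
#'
#' Rank-based mapping of data values to standard-normal quantiles
#' (`qnorm((rank - 0.5) / n)`, average ranks for ties), with linear
#' interpolation between data quantiles and linear tail extrapolation on
#' inversion.  Forward-then-inverse reproduces the data.
#'
#' @param values numeric data vector.
#' @return a `normal_score_map` object.
#' @export
normal_score_map <- function(values) {
  if (any(!is.finite(values))) stopf("normal_score_map needs finite values")
  n <- length(values)
  if (n < 2) stopf("need at least 2 values")
  r <- rank(values, ties.method = "average")
  z <- qnorm((r - 0.5) / n)
  o <- order(values)
  vs <- values[o]
  zs <- z[o]
  # collapse ties so the interpolation table is strictly monotone
  keep <- !duplicated(vs)
  structure(list(values = vs[keep], scores = zs[keep], n = n),
            class = "normal_score_map")
}

#' Forward normal-score transform
#' @param map a [normal_score_map].
#' @param values data-scale values.
#' @return standard-normal scores (linear interpolation/extrapolation
#'   between table knots).
#' @export
ns_forward <- function(map, values) {
  interp_linear(map$values, map$scores, values)
}

#' Inverse normal-score transform
#' @param map a [normal_score_map].
#' @param scores standard-normal scores.
#' @return data-scale values.
#' @export
ns_inverse <- function(map, scores) {
  interp_linear(map$scores, map$values, scores)
}

# piecewise-linear interpolation with linear tail extrapolation from the
# outermost two knots (degenerate single-knot table -> constant)
interp_linear <- function(xk, yk, x) {
  m <- length(xk)
  if (m == 1L) return(rep(yk, length(x)))
  out <- approx(xk, yk, xout = x, rule = 2)$y
  lo <- x < xk[1]
  hi <- x > xk[m]
  if (any(lo)) {
    s <- (yk[2] - yk[1]) / (xk[2] - xk[1])
    out[lo] <- yk[1] + s * (x[lo] - xk[1])
  }
  if (any(hi)) {
    s <- (yk[m] - yk[m - 1]) / (xk[m] - xk[m - 1])
    out[hi] <- yk[m] + s * (x[hi] - xk[m])
  }
  out
}
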