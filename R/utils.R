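#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds R's RNG with `seed`, evaluates `code`
#' and restores the previous state, so package functions taking a `seed`
#' argument never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1) # materialize a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a root seed
#'
#' Counter-based splitting: the same (root, counter) pair always yields the
#' same sub-seed, and results stay inside the 32-bit signed range R's
#' `set.seed` accepts.
#'
#' @param seed root integer seed.
#' @param counter non-negative integer stream index.
#' @return integer sub-seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, counter) {
  s <- (abs(as.double(seed)) %% 1048573) * 2039 + as.double(counter) * 7919 + 17
  as.integer(s %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[laiscape] ", fmt), ...))
}

# half-open pixel ownership: x in [(c-1)*ps, c*ps) belongs to column c;
# origin is the top-left grid corner, y increasing down the rows
point_to_pixel <- function(x, y, pixel_size, nrow, ncol) {
  col <- floor(x / pixel_size) + 1L
  row <- floor(y / pixel_size) + 1L
  inside <- col >= 1L & col <= ncol & row >= 1L & row <= nrow
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

pixel_center <- function(row, col, pixel_size) {
  list(x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size)
}
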