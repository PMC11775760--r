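#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange (readable by GIS software); the matrix's
#' first row is the grid's northern edge.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param pixel_size cell size, metres.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata nodata marker written for `NA`.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, pixel_size, xll = 0, yll = 0,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", pixel_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m[is.na(m)] <- nodata
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII
#'   raster).
#' @return list with `matrix`, `pixel_size`, `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- vapply(kv, function(x) as.numeric(x[2]), 0)
  names(vals) <- tolower(vapply(kv, `[`, "", 1))
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  list(matrix = m, pixel_size = vals[["cellsize"]],
       xll = vals[["xllcorner"]], yll = vals[["yllcorner"]])
}

#' Write a JSON run manifest
#'
#' @param path output path.
#' @param ... named entries (inputs, seeds, settings).  The package
#'   version and timestamp are added.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$package <- "laiscape"
  entries$version <- as.character(utils::packageVersion("laiscape"))
  entries$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
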