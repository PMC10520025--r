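#' Create an in-memory raster
#'
#' A minimal single-band raster in a projected metric coordinate system.
#' Values are stored as a matrix whose rows run south to north, so
#' `values[i, j]` is the cell in the i-th row from the bottom edge and the
#' j-th column from the left edge.
#'
#' @param values numeric matrix of cell values (rows = y increasing, cols = x
#'   increasing). `NA` marks missing cells.
#' @param xll,yll coordinates of the lower-left corner of the grid, in meters.
#' @param res cell size in meters.
#' @return An object of class `scr_raster`.
#' @export
scr_raster <- function(values, xll = 0, yll = 0, res = 25) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("raster values must be numeric")
  if (!is.numeric(res) || length(res) != 1L || res <= 0)
    stopf("res must be a single positive number")
  structure(list(values = values, xll = xll, yll = yll, res = res),
            class = "scr_raster")
}

#' @export
print.scr_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<scr_raster> %d x %d cells, %g m resolution\n",
              nrow(v), ncol(v), x$res))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$xll, x$xll + ncol(v) * x$res, x$yll, x$yll + nrow(v) * x$res))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d missing\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
plot.scr_raster <- function(x, main = deparse(substitute(x)), ...) {
  xs <- x$xll + (seq_len(ncol(x$values)) - 0.5) * x$res
  ys <- x$yll + (seq_len(nrow(x$values)) - 0.5) * x$res
  graphics::image(xs, ys, t(x$values), asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, ...)
  invisible(x)
}

#' Cell-center coordinates of a raster
#'
#' @param r an [scr_raster].
#' @return A two-column matrix of (x, y) centers, one row per cell, in
#'   column-major order of the value matrix.
#' @export
rasterCenters <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cbind(x = rep(r$xll + (seq_len(nc) - 0.5) * r$res, each = nr),
        y = rep(r$yll + (seq_len(nr) - 0.5) * r$res, times = nc))
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from north to south.
#'
#' @param path file path.
#' @return `read_asc()` returns an [scr_raster]; `write_asc()` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stopf("malformed ESRI ASCII header in %s", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stopf("expected %d values, found %d", hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  # file rows are north->south; internal storage is south->north
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  scr_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner, res = hdr$cellsize)
}

#' @rdname read_asc
#' @param r an [scr_raster] to write.
#' @param nodata value substituted for `NA` cells.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xll),
           sprintf("yllcorner %.10g", r$yll),
           sprintf("cellsize %.10g", r$res),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                function(row) paste(format(row, trim = TRUE, digits = 10),
                                    collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
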