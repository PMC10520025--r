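#' Terrain ruggedness index (TRI)
#'
#' Per-cell elevation heterogeneity: the square root of the summed squared
#' elevation differences between a cell and its (up to) eight adjacent cells.
#' Edge cells use the neighbors that exist; missing neighbors are skipped.
#'
#' @param dem an [scr_raster] digital elevation model.
#' @return An [scr_raster] of TRI values on the same grid.
#' @export
computeTRI <- function(dem) {
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stopf("DEM must have at least 3 x 3 cells")
  if (all(is.na(z))) stopf("DEM has no non-missing values")
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    src_i <- intersect(seq_len(nr) + di, seq_len(nr))
    src_j <- intersect(seq_len(nc) + dj, seq_len(nc))
    tgt_i <- src_i - di; tgt_j <- src_j - dj
    d <- z[src_i, src_j, drop = FALSE] - z[tgt_i, tgt_j, drop = FALSE]
    d[is.na(d)] <- 0
    acc[tgt_i, tgt_j] <- acc[tgt_i, tgt_j] + d * d
  }
  out <- sqrt(acc)
  out[is.na(z)] <- NA
  scr_raster(out, xll = dem$xll, yll = dem$yll, res = dem$res)
}

# Horn (1981) eight-neighbor slope and aspect. Returns slope in radians and
# aspect in degrees clockwise from north (direction the slope faces, i.e. the
# downhill azimuth); aspect of flat cells is NA. Edge rows/columns are handled
# by clamping indices (replicated edge).
horn_slope_aspect <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); res <- dem$res
  up <- function(i) pmin(i + 1L, nr); dn <- function(i) pmax(i - 1L, 1L)
  rt <- function(j) pmin(j + 1L, nc); lf <- function(j) pmax(j - 1L, 1L)
  I <- seq_len(nr); J <- seq_len(nc)
  zN <- z[up(I), J]; zS <- z[dn(I), J]; zE <- z[I, rt(J)]; zW <- z[I, lf(J)]
  zNE <- z[up(I), rt(J)]; zNW <- z[up(I), lf(J)]
  zSE <- z[dn(I), rt(J)]; zSW <- z[dn(I), lf(J)]
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * res)
  dzdy <- ((zNE + 2 * zN + zNW) - (zSE + 2 * zS + zSW)) / (8 * res)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[slope == 0] <- NA
  list(slope = slope, aspect = aspect)
}

#' Site severity index (SSI)
#'
#' A slope-aspect composite used as a proxy for thermal site conditions:
#' `SSI = sin(slope) * cos(aspect - 180 deg)` with aspect measured in degrees
#' clockwise from north. Steep south-facing slopes (xeric) score positive,
#' steep north-facing slopes (mesic) negative, flat terrain zero. Slope and
#' aspect are estimated from the DEM by the Horn eight-neighbor method. The
#' index definition is configurable via `fun` should a different slope-aspect
#' composite be preferred.
#'
#' @param dem an [scr_raster] digital elevation model.
#' @param fun function of `(slope_rad, aspect_deg)` returning the index;
#'   the default implements `sin(slope) * cos(aspect - 180)`.
#' @return An [scr_raster] of SSI values.
#' @export
computeSSI <- function(dem,
                       fun = function(slope, aspect)
                         sin(slope) * cos((aspect - 180) * pi / 180)) {
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) stopf("DEM must have at least 3 x 3 cells")
  if (all(is.na(z))) stopf("DEM has no non-missing values")
  sa <- horn_slope_aspect(dem)
  out <- fun(sa$slope, sa$aspect)
  out[sa$slope == 0] <- 0          # flat: aspect undefined, severity zero
  out[is.na(z)] <- NA
  scr_raster(out, xll = dem$xll, yll = dem$yll, res = dem$res)
}

#' Circular moving-window average
#'
#' Replaces each cell by the mean of all cells whose centers lie within
#' `radius` meters of its center (the cell itself included). Missing cells are
#' excluded from the mean.
#'
#' @param r an [scr_raster].
#' @param radius window radius in meters; must be at least the raster
#'   resolution.
#' @return An [scr_raster] of window means.
#' @export
windowAverage <- function(r, radius) {
  if (radius < r$res) stopf("radius (%g m) must be >= raster resolution (%g m)", radius, r$res)
  z <- r$values
  nr <- nrow(z); nc <- ncol(z)
  kmax <- floor(radius / r$res)
  sums <- matrix(0, nr, nc); cnts <- matrix(0, nr, nc)
  ok <- !is.na(z)
  z0 <- z; z0[!ok] <- 0
  for (di in -kmax:kmax) for (dj in -kmax:kmax) {
    if ((di * di + dj * dj) * r$res^2 > radius^2 + 1e-9) next
    src_i <- intersect(seq_len(nr) + di, seq_len(nr))
    src_j <- intersect(seq_len(nc) + dj, seq_len(nc))
    tgt_i <- src_i - di; tgt_j <- src_j - dj
    sums[tgt_i, tgt_j] <- sums[tgt_i, tgt_j] + z0[src_i, src_j, drop = FALSE]
    cnts[tgt_i, tgt_j] <- cnts[tgt_i, tgt_j] + ok[src_i, src_j, drop = FALSE]
  }
  out <- sums / cnts
  out[cnts == 0] <- NA
  scr_raster(out, xll = r$xll, yll = r$yll, res = r$res)
}

# Standardize matrix columns to mean 0, sd 1; returns list(X, mean, sd).
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  if (any(sdev == 0)) stopf("cannot standardize constant column '%s'",
                            colnames(X)[which(sdev == 0)[1]])
  list(X = sweep(sweep(X, 2L, mu), 2L, sdev, "/"), mean = mu, sd = sdev)
}

#' Build the discretized habitat state space
#'
#' Computes TRI and SSI from the DEM, window-averages all covariates within
#' `radius`, aggregates them to a coarse habitat grid of `cell` meters snapped
#' to multiples of the cell size, restricts the grid to the study-area polygon
#' grown by `buffer` meters, and standardizes each covariate to mean zero and
#' unit standard deviation. Buffering is grid-based: a habitat cell is kept if
#' its center lies within `buffer` meters (per axis) of the center of a cell
#' inside the polygon, so the buffered grid always contains the polygon.
#'
#' @param polygon two-column matrix of study-area vertices (meters).
#' @param rasters named list of [scr_raster]s on a common 25 m grid:
#'   `dem` (m), `canopy` (percent), `barren` (percent), `forest`
#'   (binary land-cover layer).
#' @param buffer buffer width in meters (default 1000).
#' @param cell habitat cell size in meters (default 250).
#' @param radius covariate averaging radius in meters, matched to the local
#'   home-range scale (200 where home ranges are small, 300 where they are
#'   larger; default 200).
#' @return An object of class `habitat_grid` with elements `centers` (n x 2),
#'   `cell_size`, `cell_area_km2`, `X` (standardized covariates TRI, SSI,
#'   CANOPY, BARREN), `forest` (logical), `in_study` (logical: center inside
#'   the unbuffered polygon), `buffer`, `standardization` (means and sds).
#' @export
buildHabitatGrid <- function(polygon, rasters, buffer = 1000, cell = 250,
                             radius = 200) {
  need <- c("dem", "canopy", "barren", "forest")
  miss <- setdiff(need, names(rasters))
  if (length(miss)) stopf("missing raster layer(s): %s", paste(miss, collapse = ", "))
  polygon <- as.matrix(polygon)

  smoothed <- list(
    TRI    = windowAverage(computeTRI(rasters$dem), radius),
    SSI    = windowAverage(computeSSI(rasters$dem), radius),
    CANOPY = windowAverage(rasters$canopy, radius),
    BARREN = windowAverage(rasters$barren, radius))

  # candidate coarse lattice snapped to multiples of `cell`, covering the
  # buffered polygon bounding box
  x0 <- floor((min(polygon[, 1]) - buffer) / cell) * cell
  x1 <- ceiling((max(polygon[, 1]) + buffer) / cell) * cell
  y0 <- floor((min(polygon[, 2]) - buffer) / cell) * cell
  y1 <- ceiling((max(polygon[, 2]) + buffer) / cell) * cell
  cx <- seq(x0 + cell / 2, x1 - cell / 2, by = cell)
  cy <- seq(y0 + cell / 2, y1 - cell / 2, by = cell)
  centers <- cbind(x = rep(cx, each = length(cy)), y = rep(cy, times = length(cx)))

  inside <- pointInPolygon(centers, polygon)
  if (!any(inside)) stopf("no habitat cell centers fall inside the polygon")
  keep <- inside
  if (buffer > 0) {
    ins <- centers[inside, , drop = FALSE]
    for (i in which(!inside)) {
      cheb <- pmax(abs(ins[, 1] - centers[i, 1]), abs(ins[, 2] - centers[i, 2]))
      if (min(cheb) <= buffer + 1e-9) keep[i] <- TRUE
    }
  }
  centers <- centers[keep, , drop = FALSE]
  in_study <- inside[keep]

  # mean-aggregate each smoothed 25 m layer to the kept coarse cells
  agg <- function(layer, name) {
    fc <- rasterCenters(layer)
    v <- as.vector(layer$values)
    ix <- floor((fc[, 1] - x0) / cell)
    iy <- floor((fc[, 2] - y0) / cell)
    fkey <- paste(ix, iy)
    ckey <- paste(floor((centers[, 1] - x0) / cell), floor((centers[, 2] - y0) / cell))
    sums <- tapply(v, fkey, sum, na.rm = TRUE)
    cnts <- tapply(!is.na(v), fkey, sum)
    out <- as.numeric(sums[ckey] / cnts[ckey])
    if (any(!is.finite(out)))
      stopf("raster coverage gap: covariate '%s' has no data in %d habitat cell(s)",
            name, sum(!is.finite(out)))
    out
  }
  Xraw <- cbind(TRI = agg(smoothed$TRI, "TRI"),
                SSI = agg(smoothed$SSI, "SSI"),
                CANOPY = agg(smoothed$CANOPY, "CANOPY"),
                BARREN = agg(smoothed$BARREN, "BARREN"))
  forest <- agg(rasters$forest, "forest") >= 0.5
  std <- standardize_columns(Xraw)

  structure(list(centers = centers, cell_size = cell,
                 cell_area_km2 = (cell / 1000)^2,
                 X = std$X, forest = forest, in_study = in_study,
                 buffer = buffer,
                 standardization = list(mean = std$mean, sd = std$sd)),
            class = "habitat_grid")
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat(sprintf("<habitat_grid> %d cells of %g m (%g km2 each), buffer %g m\n",
              nrow(x$centers), x$cell_size, x$cell_area_km2, x$buffer))
  cat(sprintf("  covariates: %s (standardized)\n", paste(colnames(x$X), collapse = ", ")))
  cat(sprintf("  forest cells: %d; cells inside study area: %d\n",
              sum(x$forest), sum(x$in_study)))
  invisible(x)
}

#' Number of habitat cells
#' @param habitat a `habitat_grid`.
#' @export
nCells <- function(habitat) nrow(habitat$centers)

#' Iterative collinearity screen
#'
#' While any pair of columns has `|Pearson r|` strictly above `threshold`,
#' drops from the worst pair the column with the larger mean absolute
#' correlation to all remaining columns (the later column on ties).
#'
#' @param X numeric matrix of candidate covariates (named columns).
#' @param threshold correlation magnitude above which a pair is collinear
#'   (default 0.7; pairs at exactly the threshold are kept).
#' @return List with `kept` (column names retained), `dropped` (data frame
#'   logging each removal and the offending pair), and `X` (the filtered
#'   matrix).
#' @export
collinearityFilter <- function(X, threshold = 0.7) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stopf("need at least two columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (any(apply(X, 2L, sd) == 0))
    stopf("constant column '%s' has zero variance",
          colnames(X)[which(apply(X, 2L, sd) == 0)[1]])
  dropped <- data.frame(dropped = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(X) < 2L) break
    R <- abs(cor(X)); diag(R) <- 0
    worst <- max(R)
    if (worst <= threshold) break
    idx <- which(R == worst, arr.ind = TRUE)[1, ]
    meanabs <- rowSums(R) / (ncol(X) - 1L)
    pair <- sort(c(idx[["row"]], idx[["col"]]))
    drop_i <- if (meanabs[pair[1]] > meanabs[pair[2]]) pair[1] else pair[2]
    keep_i <- setdiff(pair, drop_i)
    dropped <- rbind(dropped, data.frame(
      dropped = colnames(X)[drop_i], partner = colnames(X)[keep_i],
      r = cor(X[, drop_i], X[, keep_i]), stringsAsFactors = FALSE))
    X <- X[, -drop_i, drop = FALSE]
  }
  list(kept = colnames(X), dropped = dropped, X = X)
}
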