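#' Construct a detector grid directly
#'
#' Detectors are "conceptual traps": grid cells of the search area treated as
#' passive detectors. Each carries the number of searched 50 m sub-cells
#' (`K`, the binomial trial count, 1-4) and a search-effort covariate
#' (standardized log searched area).
#'
#' @param x,y detector cell-center coordinates in meters.
#' @param K integer trial counts in 1..4 (searched sub-cells per cell).
#' @param effort_raw searched area per detector in m^2 (0 < effort <= cell
#'   area).
#' @param cell_size detector cell size in meters (default 100).
#' @param sub_cells optional list (one entry per detector) of integer ids in
#'   1..4 naming which quadrant sub-cells were searched; defaults to
#'   `1:K[j]`.
#' @return An object of class `detector_grid`: a data frame with columns
#'   `detector_id`, `x`, `y`, `K`, `effort_raw`, `effort_std` and attributes
#'   `cell_size`, `sub_cell_size`, `sub_cells`.
#' @export
detectorGrid <- function(x, y, K, effort_raw, cell_size = 100,
                         sub_cells = NULL) {
  n <- length(x)
  K <- as.integer(K)
  if (length(y) != n || length(K) != n || length(effort_raw) != n)
    stopf("x, y, K, effort_raw must have equal length")
  if (n == 0L) stopf("detector grid is empty")
  if (any(K < 1L | K > 4L)) stopf("K must be in 1..4")
  if (any(effort_raw <= 0 | effort_raw > cell_size^2 + 1e-6))
    stopf("effort_raw must satisfy 0 < effort_raw <= cell area (%g m^2)", cell_size^2)
  le <- log(effort_raw)
  effort_std <- if (n > 1L && sd(le) > 0) (le - mean(le)) / sd(le) else rep(0, n)
  if (is.null(sub_cells)) sub_cells <- lapply(K, seq_len)
  d <- data.frame(detector_id = seq_len(n), x = x, y = y, K = K,
                  effort_raw = effort_raw, effort_std = effort_std)
  structure(d, class = c("detector_grid", "data.frame"),
            cell_size = cell_size, sub_cell_size = cell_size / 2,
            sub_cells = sub_cells)
}

#' @export
print.detector_grid <- function(x, ...) {
  cat(sprintf("<detector_grid> %d conceptual traps of %g m, K in [%d, %d]\n",
              nrow(x), attr(x, "cell_size"), min(x$K), max(x$K)))
  cat(sprintf("  searched area: %.0f - %.0f m^2 per trap\n",
              min(x$effort_raw), max(x$effort_raw)))
  invisible(x)
}

# Quadrant sub-cell centers of a detector cell: ids 1..4 = SW, SE, NW, NE.
sub_cell_centers <- function(cx, cy, cell_size) {
  q <- cell_size / 4
  cbind(x = cx + c(-q, q, -q, q), y = cy + c(-q, -q, q, q))
}

#' Derive conceptual traps from search tracks
#'
#' Buffers each ordered GPS track by `track_buffer` meters (the approximate
#' viewshed of the observers), rasterizes the buffered corridor at
#' `fine_res` meters, and overlays a detector grid of `main_cell` meters
#' subdivided into four `sub_cell` sub-cells. A sub-cell counts as searched if
#' any fine raster point inside the study polygon falls in the buffered
#' corridor; unsearched main cells are not part of the returned grid. Searched
#' area per detector is the rasterized buffer-cell intersection area.
#'
#' @param tracks data frame with columns `track_id`, `x`, `y`; rows ordered
#'   along each track. Coordinates in a projected metric CRS.
#' @param polygon study-area polygon (two-column matrix).
#' @param main_cell detector cell size, meters (default 100).
#' @param sub_cell sub-cell size, meters (default `main_cell / 2`).
#' @param track_buffer half-width of the searched corridor, meters (default 3).
#' @param fine_res rasterization resolution for the effort area, meters
#'   (default 1).
#' @return A [detectorGrid()] object; empty tracks inside the polygon trigger
#'   a warning and an error is raised for degenerate single-point tracks.
#' @export
buildDetectors <- function(tracks, polygon, main_cell = 100,
                           sub_cell = main_cell / 2, track_buffer = 3,
                           fine_res = 1) {
  stopifnot(all(c("track_id", "x", "y") %in% names(tracks)))
  if (sub_cell * 2 != main_cell)
    stopf("sub_cell must be half of main_cell (four sub-cells per detector)")
  polygon <- as.matrix(polygon)
  npts <- table(tracks$track_id)
  if (any(npts < 2L))
    stopf("degenerate single-point track(s): %s",
          paste(names(npts)[npts < 2L], collapse = ", "))

  # collect searched fine-grid cells (integer indices on a global fine lattice)
  searched <- new.env(hash = TRUE, parent = emptyenv())
  for (tid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == tid, , drop = FALSE]
    for (s in seq_len(nrow(tr) - 1L)) {
      x1 <- tr$x[s]; y1 <- tr$y[s]; x2 <- tr$x[s + 1L]; y2 <- tr$y[s + 1L]
      ix <- seq(floor((min(x1, x2) - track_buffer) / fine_res),
                ceiling((max(x1, x2) + track_buffer) / fine_res))
      iy <- seq(floor((min(y1, y2) - track_buffer) / fine_res),
                ceiling((max(y1, y2) + track_buffer) / fine_res))
      px <- rep((ix + 0.5) * fine_res, times = length(iy))
      py <- rep((iy + 0.5) * fine_res, each = length(ix))
      hit <- dist_to_segment(px, py, x1, y1, x2, y2) <= track_buffer
      if (!any(hit)) next
      keys <- paste(rep(ix, times = length(iy))[hit],
                    rep(iy, each = length(ix))[hit])
      for (k in keys) assign(k, TRUE, envir = searched)
    }
  }
  keys <- ls(searched)
  if (length(keys) == 0L) {
    warning("tracks produced no searched area; returning empty grid")
    return(structure(data.frame(detector_id = integer(), x = numeric(),
                                y = numeric(), K = integer(),
                                effort_raw = numeric(), effort_std = numeric()),
                     class = c("detector_grid", "data.frame"),
                     cell_size = main_cell, sub_cell_size = sub_cell,
                     sub_cells = list()))
  }
  ij <- do.call(rbind, strsplit(keys, " "))
  fx <- (as.numeric(ij[, 1]) + 0.5) * fine_res
  fy <- (as.numeric(ij[, 2]) + 0.5) * fine_res
  inside <- pointInPolygon(cbind(fx, fy), polygon)
  if (!any(inside)) {
    warning("all searched area lies outside the study polygon; returning empty grid")
    return(structure(data.frame(detector_id = integer(), x = numeric(),
                                y = numeric(), K = integer(),
                                effort_raw = numeric(), effort_std = numeric()),
                     class = c("detector_grid", "data.frame"),
                     cell_size = main_cell, sub_cell_size = sub_cell,
                     sub_cells = list()))
  }
  fx <- fx[inside]; fy <- fy[inside]

  main_ix <- floor(fx / main_cell); main_iy <- floor(fy / main_cell)
  sub_ix <- floor(fx / sub_cell) %% 2L; sub_iy <- floor(fy / sub_cell) %% 2L
  sub_id <- 1L + sub_ix + 2L * sub_iy          # 1=SW, 2=SE, 3=NW, 4=NE
  mkey <- paste(main_ix, main_iy)
  cells <- sort(unique(mkey))
  Ks <- integer(length(cells)); eff <- numeric(length(cells))
  subs <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    sel <- mkey == cells[i]
    subs[[i]] <- sort(unique(sub_id[sel]))
    Ks[i] <- length(subs[[i]])
    eff[i] <- sum(sel) * fine_res^2
  }
  ij2 <- do.call(rbind, strsplit(cells, " "))
  cx <- (as.numeric(ij2[, 1]) + 0.5) * main_cell
  cy <- (as.numeric(ij2[, 2]) + 0.5) * main_cell
  detectorGrid(cx, cy, Ks, pmin(eff, main_cell^2), cell_size = main_cell,
               sub_cells = subs)
}

#' Assemble individual encounter histories
#'
#' Assigns each genotyped detection to the detector cell and 50 m sub-cell
#' containing it. Within one detector an individual scores at most one
#' encounter per searched sub-cell, so `y[i, j]` is the number of distinct
#' searched sub-cells of detector `j` holding samples of individual `i`
#' (never exceeding `K[j]`). Samples falling in unsearched cells or
#' unsearched sub-cells are dropped and reported in the `dropped` attribute.
#'
#' @param samples data frame with columns `individual_id`, `sex`
#'   (`"F"`, `"M"`, or `NA`/`"U"` for unknown), `x`, `y`.
#' @param detectors a [detectorGrid()].
#' @return An object of class `encounter_data`: list with `y` (individuals x
#'   detectors count matrix), `ids`, `sex` (0 female / 1 male / NA unknown),
#'   `detections` (per-sample rows retained), and `dropped` (rows removed,
#'   with reasons).
#' @export
assignDetections <- function(samples, detectors) {
  stopifnot(all(c("individual_id", "sex", "x", "y") %in% names(samples)))
  if (nrow(detectors) == 0L) stopf("detector grid is empty")
  if (any(!is.finite(samples$x) | !is.finite(samples$y)))
    stopf("non-finite coordinates in rows: %s",
          paste(which(!is.finite(samples$x) | !is.finite(samples$y)), collapse = ", "))
  cs <- attr(detectors, "cell_size"); ss <- attr(detectors, "sub_cell_size")
  dkey <- paste(floor(detectors$x / cs), floor(detectors$y / cs))
  skey <- paste(floor(samples$x / cs), floor(samples$y / cs))
  det_idx <- match(skey, dkey)
  sub_id <- 1L + (floor(samples$x / ss) %% 2L) + 2L * (floor(samples$y / ss) %% 2L)
  sub_ok <- mapply(function(j, s) !is.na(j) && s %in% attr(detectors, "sub_cells")[[j]],
                   det_idx, sub_id)
  reason <- ifelse(is.na(det_idx), "unsearched detector cell",
                   ifelse(sub_ok, NA, "unsearched sub-cell"))
  dropped <- cbind(samples[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  keep <- is.na(reason)
  samples <- samples[keep, , drop = FALSE]
  det_idx <- det_idx[keep]; sub_id <- sub_id[keep]

  ids <- sort(unique(samples$individual_id))
  sex <- vapply(ids, function(id) {
    s <- unique(stats::na.omit(samples$sex[samples$individual_id == id &
                                             samples$sex %in% c("F", "M")]))
    if (length(s) > 1L) stopf("conflicting sex labels for individual '%s'", id)
    if (length(s) == 0L) NA_real_ else if (s == "M") 1 else 0
  }, numeric(1))

  y <- matrix(0L, nrow = length(ids), ncol = nrow(detectors),
              dimnames = list(ids, detectors$detector_id))
  if (nrow(samples)) {
    enc <- unique(data.frame(i = match(samples$individual_id, ids),
                             j = det_idx, s = sub_id))
    for (r in seq_len(nrow(enc))) y[enc$i[r], enc$j[r]] <- y[enc$i[r], enc$j[r]] + 1L
  }
  detections <- data.frame(individual_id = samples$individual_id,
                           detector_id = detectors$detector_id[det_idx],
                           sub_cell = sub_id, x = samples$x, y = samples$y)
  encounterData(y, ids, sex, detections, dropped = dropped)
}

# internal constructor shared by assignDetections / simulateSurvey / filter
encounterData <- function(y, ids, sex, detections, dropped = NULL,
                          applied_cap = NULL) {
  structure(list(y = y, ids = ids, sex = sex, detections = detections,
                 dropped = dropped, applied_cap = applied_cap),
            class = "encounter_data")
}

#' @export
print.encounter_data <- function(x, ...) {
  cat(sprintf("<encounter_data> %d individuals, %d detectors, %d encounters\n",
              nrow(x$y), ncol(x$y), sum(x$y)))
  cat(sprintf("  sex: %d F, %d M, %d unknown\n",
              sum(x$sex == 0, na.rm = TRUE), sum(x$sex == 1, na.rm = TRUE),
              sum(is.na(x$sex))))
  if (!is.null(x$applied_cap))
    cat(sprintf("  long-recapture cap applied: %.1f m\n", x$applied_cap))
  invisible(x)
}

#' Remove implausibly long spatial recaptures
#'
#' Pools all within-individual pairwise detection distances, sets the cap at
#' the given percentile of that pooled distribution (or at `cap` if supplied),
#' and then, while any individual still has a pairwise distance above the cap,
#' removes that individual's detection with the largest mean distance to its
#' other detections. Individuals reduced to a single detection are kept.
#'
#' @param enc an `encounter_data` with a `detections` table.
#' @param percentile percentile of the pooled recapture-distance distribution
#'   used as the cap (default 99; linear-interpolation empirical quantile).
#' @param cap optional explicit distance cap in meters, overriding the
#'   percentile rule (e.g. a previously derived 1500 m cap).
#' @return A filtered `encounter_data`; attribute fields `applied_cap` and
#'   `removed` (data frame of removed detections) record what was done.
#' @export
filterLongRecaptures <- function(enc, percentile = 99, cap = NULL) {
  det <- enc$detections
  pool <- recapture_distances(det)
  if (length(pool) == 0L) {
    message("no spatial recaptures; nothing to filter")
    return(enc)
  }
  if (is.null(cap)) cap <- unname(quantile(pool, percentile / 100, type = 7))
  removed <- det[0, , drop = FALSE]
  for (id in unique(det$individual_id)) {
    repeat {
      rows <- which(det$individual_id == id)
      if (length(rows) < 2L) break
      D <- as.matrix(dist(det[rows, c("x", "y")]))
      if (max(D) <= cap) break
      worst <- rows[which.max(rowSums(D) / (length(rows) - 1L))]
      removed <- rbind(removed, det[worst, , drop = FALSE])
      det <- det[-worst, , drop = FALSE]
    }
  }
  out <- rebuild_counts(det, enc)
  out$applied_cap <- cap
  out$removed <- removed
  out
}

# pooled within-individual pairwise detection distances
recapture_distances <- function(det) {
  unlist(lapply(split(det[, c("x", "y")], det$individual_id), function(p) {
    if (nrow(p) < 2L) numeric(0) else as.vector(dist(p))
  }), use.names = FALSE)
}

# rebuild the count matrix from a detections table, keeping detector columns
rebuild_counts <- function(det, enc) {
  ids <- sort(unique(det$individual_id))
  y <- matrix(0L, nrow = length(ids), ncol = ncol(enc$y),
              dimnames = list(ids, colnames(enc$y)))
  if (nrow(det)) {
    u <- unique(det[, c("individual_id", "detector_id", "sub_cell")])
    i <- match(u$individual_id, ids)
    j <- match(as.character(u$detector_id), colnames(enc$y))
    for (r in seq_along(i)) y[i[r], j[r]] <- y[i[r], j[r]] + 1L
  }
  sex <- enc$sex[match(ids, enc$ids)]
  encounterData(y, ids, sex, det, dropped = enc$dropped)
}
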