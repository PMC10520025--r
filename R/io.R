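#' Read search tracks
#'
#' `readTracksCSV()` expects columns `track_id`, `order` (or pre-sorted
#' rows), `x`, `y` in a projected metric CRS. `readTracksGPX()` reads the
#' track segments of a GPX file; GPX stores lat/lon, so a projection function
#' mapping `(lon, lat)` to metric `(x, y)` must be supplied.
#'
#' @param path file path.
#' @return Data frame with columns `track_id`, `x`, `y`, ordered along each
#'   track.
#' @export
readTracksCSV <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("track_id", "x", "y") %in% names(d)))
  if ("order" %in% names(d)) d <- d[order(d$track_id, d$order), ]
  d[, c("track_id", "x", "y")]
}

#' @rdname readTracksCSV
#' @param project function `(lon, lat) -> list/cbind(x, y)` projecting
#'   geographic coordinates to the metric working CRS.
#' @export
readTracksGPX <- function(path, project) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  segs <- xml2::xml_find_all(doc, ".//g:trkseg", ns)
  out <- lapply(seq_along(segs), function(i) {
    pts <- xml2::xml_find_all(segs[[i]], ".//g:trkpt", ns)
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    xy <- project(lon, lat)
    data.frame(track_id = i, x = xy[[1]], y = xy[[2]])
  })
  do.call(rbind, out)
}

#' Write the habitat grid to CSV with a JSON sidecar
#'
#' The CSV holds one row per habitat cell (`cell_id`, `x`, `y`, the four
#' standardized covariates, `forest`, `in_study`); the sidecar
#' (`<path>.json`) records cell size, buffer, and the standardization means
#' and standard deviations needed to map new covariate values onto the model
#' scale.
#'
#' @param habitat a `habitat_grid`.
#' @param path CSV output path.
#' @export
writeHabitatCSV <- function(habitat, path) {
  d <- data.frame(cell_id = seq_len(nCells(habitat)),
                  x = habitat$centers[, 1], y = habitat$centers[, 2],
                  habitat$X, forest = habitat$forest,
                  in_study = habitat$in_study)
  write.csv(d, path, row.names = FALSE)
  side <- list(cell_size = habitat$cell_size,
               cell_area_km2 = habitat$cell_area_km2,
               buffer = habitat$buffer,
               standardization = habitat$standardization,
               crs = "projected metric (meters)")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a habitat grid written by [writeHabitatCSV()]
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @export
readHabitatCSV <- function(path) {
  d <- read.csv(path)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(centers = cbind(x = d$x, y = d$y),
                 cell_size = side$cell_size,
                 cell_area_km2 = side$cell_area_km2,
                 X = as.matrix(d[, c("TRI", "SSI", "CANOPY", "BARREN")]),
                 forest = as.logical(d$forest),
                 in_study = as.logical(d$in_study),
                 buffer = side$buffer,
                 standardization = side$standardization),
            class = "habitat_grid")
}

#' Write detectors and encounters to CSV
#'
#' @param detectors a [detectorGrid()].
#' @param enc an `encounter_data`.
#' @param path output path.
#' @export
writeDetectorCSV <- function(detectors, path) {
  write.csv(as.data.frame(detectors), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDetectorCSV
#' @export
writeEncounterCSV <- function(enc, path) {
  long <- which(enc$y > 0L, arr.ind = TRUE)
  d <- data.frame(individual_id = rownames(enc$y)[long[, 1]],
                  sex = ifelse(is.na(enc$sex[long[, 1]]), "U",
                               ifelse(enc$sex[long[, 1]] == 1, "M", "F")),
                  detector_id = colnames(enc$y)[long[, 2]],
                  count = enc$y[long])
  write.csv(d[order(d$individual_id, d$detector_id), ], path, row.names = FALSE)
  invisible(path)
}
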