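# Planar geometry helpers for a projected metric CRS. The package deals only
# with Euclidean coordinates in meters; geographic (lat/lon) input is the
# caller's responsibility to project first.

#' Test which points fall inside a polygon
#'
#' @param pts two-column matrix of (x, y) points.
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @return Logical vector, one entry per point.
#' @export
pointInPolygon <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  if (ncol(pts) != 2L || ncol(poly) != 2L)
    stopf("points and polygon must have two columns (x, y)")
  mgcv::in.out(rbind(poly, poly[1, ]), pts)
}

# Distance from each point to the nearest point of a segment (x1,y1)-(x2,y2).
dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance from each point to the polygon boundary.
dist_to_polygon_edges <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  n <- nrow(poly)
  d <- rep(Inf, nrow(pts))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    d <- pmin(d, dist_to_segment(pts[, 1], pts[, 2],
                                 poly[k, 1], poly[k, 2],
                                 poly[k2, 1], poly[k2, 2]))
  }
  d
}

#' Read a study-area polygon from WKT or GeoJSON
#'
#' Accepts a `POLYGON ((...))` WKT string (or a path to a file holding one)
#' or a GeoJSON file with a single Polygon geometry. Only the outer ring is
#' used; coordinates must be in a projected metric CRS.
#'
#' @param x WKT string, or path to a `.wkt`/`.geojson`/`.json` file.
#' @return Two-column matrix of vertices.
#' @export
readPolygon <- function(x) {
  txt <- x
  if (length(x) == 1L && file.exists(x)) txt <- paste(readLines(x), collapse = "\n")
  if (grepl("^\\s*\\{", txt)) {          # GeoJSON
    g <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
    geom <- g
    if (!is.null(g$features)) geom <- g$features$geometry
    if (!is.null(geom$geometry)) geom <- geom$geometry
    co <- geom$coordinates
    if (is.list(co)) co <- co[[1]]
    if (length(dim(co)) == 3L) co <- co[1, , ]
    poly <- as.matrix(co)
  } else if (grepl("POLYGON", txt, ignore.case = TRUE)) {
    inner <- sub(".*POLYGON\\s*\\(\\(", "", txt, ignore.case = TRUE)
    inner <- sub("\\)\\).*", "", inner)
    pairs <- strsplit(trimws(strsplit(inner, ",")[[1]]), "\\s+")
    poly <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  } else stopf("input is neither WKT POLYGON nor GeoJSON")
  colnames(poly) <- c("x", "y")
  # drop an explicitly closed last vertex
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}
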