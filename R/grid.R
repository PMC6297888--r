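#' Raster grid specification
#'
#' Defines a regular lon/lat (WGS84) grid, north-up with row 1 at the top.
#' All raster layers in a pipeline share one `grid_spec` so that cells are
#' aligned across layers. The default cell size is 2.5 arc minutes
#' (approximately 5 km at the equator), the working resolution of the
#' indicator pipeline; every operation is resolution-generic so tests run on
#' much coarser grids.
#'
#' @param cell_size_deg cell edge length in decimal degrees (> 0)
#' @param origin_lon,origin_lat decimal degrees of the grid's upper-left
#'   corner (corner, not first cell center)
#' @param n_rows,n_cols positive integer grid dimensions
#' @param nodata sentinel value used for missing cells
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(cell_size_deg = 2.5 / 60, origin_lon = -180,
                      origin_lat = 90, n_rows, n_cols, nodata = -9999) {
  if (!is.numeric(cell_size_deg) || length(cell_size_deg) != 1L ||
      !is.finite(cell_size_deg) || cell_size_deg <= 0) {
    stop("cell_size_deg must be a single positive number")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    stop("n_rows and n_cols must be positive integers")
  }
  structure(
    list(cell_size_deg = cell_size_deg, origin_lon = origin_lon,
         origin_lat = origin_lat, n_rows = n_rows, n_cols = n_cols,
         nodata = nodata),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.6f deg, UL corner (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$cell_size_deg, x$origin_lon, x$origin_lat))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$cell_size_deg, b$cell_size_deg)) &&
    isTRUE(all.equal(a$origin_lon, b$origin_lon)) &&
    isTRUE(all.equal(a$origin_lat, b$origin_lat)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Raster layer on a shared grid
#'
#' @param grid a [grid_spec()]
#' @param values numeric matrix of dimension `n_rows x n_cols`; use the
#'   grid's nodata sentinel (or `NA`, converted on the fly) for missing cells
#' @param semantics one of `"continuous"`, `"categorical"`, `"binary"`.
#'   Binary layers may contain only 0, 1 and nodata.
#' @return an object of class `raster_layer`
#' @export
raster_layer <- function(grid, values, semantics = c("continuous",
                                                     "categorical", "binary")) {
  stopifnot(inherits(grid, "grid_spec"))
  semantics <- match.arg(semantics)
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf("values must be %d x %d", grid$n_rows, grid$n_cols))
  }
  storage.mode(values) <- "double"
  values[is.na(values)] <- grid$nodata
  if (semantics == "binary") {
    ok <- values %in% c(0, 1, grid$nodata)
    if (!all(ok)) stop("binary layer may only contain 0, 1 or nodata")
  }
  structure(list(grid = grid, values = values, semantics = semantics),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- layer_values(x)
  cat(sprintf("<raster_layer %s> %d x %d, %d nodata cells, range [%s, %s]\n",
              x$semantics, x$grid$n_rows, x$grid$n_cols, sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

# values with nodata mapped to NA (the internal missing representation)
layer_values <- function(layer) {
  v <- layer$values
  v[v == layer$grid$nodata] <- NA_real_
  v
}

#' Geometric center of a grid cell
#'
#' Rows and columns are 1-based, row 1 at the grid's northern edge (R matrix
#' convention). The center of cell (r, c) is
#' `(origin_lon + (c - 0.5) * cell, origin_lat - (r - 0.5) * cell)`.
#'
#' @param grid a [grid_spec()]
#' @param row,col 1-based cell indices (vectorized)
#' @return a two-column matrix with columns `lon`, `lat`
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(is.na(row)) || any(is.na(col)) ||
      any(row < 1L) || any(row > grid$n_rows) ||
      any(col < 1L) || any(col > grid$n_cols)) {
    stop("cell index out of range")
  }
  cbind(lon = grid$origin_lon + (col - 0.5) * grid$cell_size_deg,
        lat = grid$origin_lat - (row - 0.5) * grid$cell_size_deg)
}

#' Cell index containing a lon/lat point
#'
#' Inverse of [cell_center()]: points on the boundary between two cells are
#' assigned to the cell to the south/east (floor semantics). Points outside
#' the grid extent get `NA` indices.
#'
#' @param grid a [grid_spec()]
#' @param lon,lat coordinates in decimal degrees (vectorized)
#' @return a two-column integer matrix with columns `row`, `col`
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size_deg) + 1L
  row <- floor((grid$origin_lat - lat) / grid$cell_size_deg) + 1L
  bad <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols |
    is.na(row) | is.na(col)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

EARTH_RADIUS_KM <- 6371
KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180  # 111.1949... km per equatorial degree

#' Equatorial edge length of a grid cell
#'
#' Great-circle length, along the equator, of one cell edge of
#' `cell_size_deg` degrees (mean Earth radius 6371 km). The pipeline's
#' default 2.5-arc-minute cell is approximately 5 km wide at the equator.
#'
#' @param cell_size_deg cell size in decimal degrees (> 0)
#' @return length in km
#' @export
cell_width_km_at_equator <- function(cell_size_deg) {
  if (!is.numeric(cell_size_deg) || any(cell_size_deg <= 0)) {
    stop("cell_size_deg must be positive")
  }
  cell_size_deg * KM_PER_DEG
}

#' Great-circle distance between points
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorized over points.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees
#' @return distance(s) in km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Polygon in geographic coordinates
#'
#' A simple polygon: one exterior ring, optional holes, and an attribute
#' list (e.g. ecoregion id, WDPA status). Rings are closed implicitly;
#' supply each ring as a two-column (lon, lat) matrix of at least three
#' distinct vertices within [-180, 180] x [-90, 90].
#'
#' @param exterior two-column matrix of exterior-ring vertices
#' @param holes list of two-column matrices (interior rings)
#' @param attrs named list of attributes
#' @return an object of class `geo_polygon`
#' @export
geo_polygon <- function(exterior, holes = list(), attrs = list()) {
  check_ring <- function(ring) {
    ring <- as.matrix(ring)
    if (ncol(ring) != 2L) stop("ring must be a two-column (lon, lat) matrix")
    storage.mode(ring) <- "double"
    # drop an explicit closing vertex; rings are closed implicitly
    n <- nrow(ring)
    if (n >= 2L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    if (nrow(unique(ring)) < 3L) stop("degenerate polygon: fewer than 3 distinct vertices")
    if (any(ring[, 1L] < -180 | ring[, 1L] > 180 |
            ring[, 2L] < -90 | ring[, 2L] > 90)) {
      stop("vertices must lie within [-180,180] x [-90,90]")
    }
    ring
  }
  structure(list(exterior = check_ring(exterior),
                 holes = lapply(holes, check_ring),
                 attrs = attrs),
            class = "geo_polygon")
}

#' Axis-aligned rectangle polygon
#'
#' Convenience constructor used heavily by the synthetic-world generator,
#' where every country, ecoregion and protected area is a rectangle so that
#' areas and memberships have closed forms.
#'
#' @param lon_min,lon_max,lat_min,lat_max rectangle bounds in degrees
#' @param attrs named attribute list
#' @return a [geo_polygon()]
#' @export
rect_polygon <- function(lon_min, lon_max, lat_min, lat_max, attrs = list()) {
  stopifnot(lon_min < lon_max, lat_min < lat_max)
  geo_polygon(cbind(c(lon_min, lon_max, lon_max, lon_min),
                    c(lat_min, lat_min, lat_max, lat_max)),
              attrs = attrs)
}

# vectorized over points: TRUE where (lon, lat) lies on any edge of `ring`
points_on_ring <- function(lon, lat, ring, tol = 1e-12) {
  n <- nrow(ring)
  on <- rep(FALSE, length(lon))
  scale <- pmax(abs(lon), abs(lat), 1)
  j <- n
  for (i in seq_len(n)) {
    x1 <- ring[j, 1L]; y1 <- ring[j, 2L]
    x2 <- ring[i, 1L]; y2 <- ring[i, 2L]
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    dot <- (lon - x1) * (x2 - x1) + (lat - y1) * (y2 - y1)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- on | (abs(cross) <= tol * scale & dot >= -tol * scale &
                  dot <= len2 + tol * scale)
    j <- i
  }
  on
}

# vectorized even-odd ray-casting crossing parity for one ring
ring_crossings <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- (yi > lat) != (yj > lat)
    if (any(crosses)) {
      x_int <- xi + (lat - yi) / (yj - yi) * (xj - xi)
      flip <- crosses & lon < x_int
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Point-in-polygon test
#'
#' Even-odd (ray casting) membership with holes. A point exactly on any
#' ring edge counts as inside — the deterministic boundary convention the
#' cell-center rasterization rule relies on. `points_in_polygon()` is the
#' vectorized form over many points.
#'
#' @param lon,lat point coordinates (scalars for [point_in_polygon()],
#'   vectors for [points_in_polygon()])
#' @param polygon a [geo_polygon()]
#' @return logical (vector)
#' @export
points_in_polygon <- function(lon, lat, polygon) {
  stopifnot(inherits(polygon, "geo_polygon"))
  boundary <- points_on_ring(lon, lat, polygon$exterior)
  for (hole in polygon$holes) {
    boundary <- boundary | points_on_ring(lon, lat, hole)
  }
  inside <- ring_crossings(lon, lat, polygon$exterior)
  for (hole in polygon$holes) {
    inside <- inside & !ring_crossings(lon, lat, hole)
  }
  boundary | inside
}

#' @rdname points_in_polygon
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  stopifnot(length(lon) == 1L, length(lat) == 1L)
  points_in_polygon(lon, lat, polygon)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange format used for all fixtures and synthetic-world
#' outputs (the pipeline has no binary raster dependency).
#'
#' @param layer a [raster_layer()]
#' @param path output file path
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  g <- layer$grid
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_lon),
    sprintf("yllcorner %.10g", g$origin_lat - g$n_rows * g$cell_size_deg),
    sprintf("cellsize %.10g", g$cell_size_deg),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  rows <- apply(layer$values, 1L, function(r) paste(format(r, trim = TRUE,
                                                           digits = 15),
                                                    collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid into a raster layer
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI .asc grid)
#' @param semantics layer semantics, see [raster_layer()]
#' @return a [raster_layer()]
#' @export
read_ascii_grid <- function(path, semantics = "continuous") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1L]][2L])
  }
  n_cols <- as.integer(val("ncols")); n_rows <- as.integer(val("nrows"))
  cell <- val("cellsize"); nodata <- val("NODATA_value")
  grid <- grid_spec(cell_size_deg = cell, origin_lon = val("xllcorner"),
                    origin_lat = val("yllcorner") + n_rows * cell,
                    n_rows = n_rows, n_cols = n_cols, nodata = nodata)
  vals <- matrix(scan(text = lines[-(1:6)], quiet = TRUE),
                 nrow = n_rows, ncol = n_cols, byrow = TRUE)
  raster_layer(grid, vals, semantics = semantics)
}

#' Write polygons to GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer (Polygon geometries with holes;
#' attributes become feature properties).
#'
#' @param polygons list of [geo_polygon()]
#' @param path output file path
#' @export
write_polygons_geojson <- function(polygons, path) {
  close_ring <- function(ring) rbind(ring, ring[1L, , drop = FALSE])
  feats <- lapply(polygons, function(p) {
    coords <- c(list(unname(apply(close_ring(p$exterior), 1L, function(v)
      list(v[1L], v[2L]), simplify = FALSE))),
      lapply(p$holes, function(h) unname(apply(close_ring(h), 1L, function(v)
        list(v[1L], v[2L]), simplify = FALSE))))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = if (length(p$attrs)) p$attrs else structure(list(), names = character(0)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Reads Polygon (and MultiPolygon, flattened) features into a list of
#' [geo_polygon()] with feature properties as attributes.
#'
#' @param path GeoJSON file
#' @return list of [geo_polygon()]
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  out <- list()
  for (feat in gj$features) {
    props <- feat$properties
    geom <- feat$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type))
    for (rings in polys) {
      mats <- lapply(rings, function(r)
        do.call(rbind, lapply(r, function(v) c(v[[1L]], v[[2L]]))))
      out[[length(out) + 1L]] <- geo_polygon(mats[[1L]],
                                             holes = mats[-1L],
                                             attrs = props)
    }
  }
  out
}
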