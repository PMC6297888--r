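#' Polygon-to-raster assignment rules
#'
#' The conservation analysis uses two distinct rasterization rules, matching
#' the two ArcGIS Polygon-to-Raster modes applied to the source layers:
#' ecoregions are assigned by the *cell center* rule (a cell takes the
#' category of the polygon containing its center) and protected areas by
#' the *maximum area* rule (a cell takes the category covering the largest
#' fraction of the cell). The two rules coincide when polygon boundaries
#' lie exactly on cell edges, and differ on partially covered cells.
#'
#' @name rasterize
NULL

poly_category <- function(p, category_attr) {
  v <- p$attrs[[category_attr]]
  if (is.null(v)) NA_integer_ else as.integer(v)
}

poly_bbox <- function(p) {
  rings <- c(list(p$exterior), p$holes)
  xs <- unlist(lapply(rings, function(r) r[, 1L]))
  ys <- unlist(lapply(rings, function(r) r[, 2L]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# rows/cols of grid cells whose centers could interact with the bbox
bbox_cells <- function(grid, bb, pad = 0) {
  cs <- grid$cell_size_deg
  col_lo <- max(1L, floor((bb["xmin"] - pad - grid$origin_lon) / cs) + 1L)
  col_hi <- min(grid$n_cols, ceiling((bb["xmax"] + pad - grid$origin_lon) / cs))
  row_lo <- max(1L, floor((grid$origin_lat - bb["ymax"] - pad) / cs) + 1L)
  row_hi <- min(grid$n_rows, ceiling((grid$origin_lat - bb["ymin"] + pad) / cs))
  if (col_lo > col_hi || row_lo > row_hi) return(NULL)
  list(rows = row_lo:row_hi, cols = col_lo:col_hi)
}

validate_polygons <- function(polygons, category_attr) {
  keep <- logical(length(polygons))
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    ok <- inherits(p, "geo_polygon") &&
      !is.na(poly_category(p, category_attr))
    if (!ok) warning(sprintf("polygon %d invalid or lacking '%s'; skipped",
                             i, category_attr))
    keep[i] <- ok
  }
  polygons[keep]
}

#' Rasterize polygons by the cell-center rule
#'
#' Each cell takes the category of the polygon containing its center; cells
#' whose center falls in no polygon are nodata. When several polygons
#' overlap a center, the earliest polygon in the list wins (deterministic
#' lowest-index tie-break). This is the rule used for the ecoregion layer.
#'
#' @param polygons list of [geo_polygon()] carrying an integer category
#'   attribute
#' @param grid a [grid_spec()]
#' @param category_attr name of the category attribute (default
#'   `"category"`)
#' @return categorical [raster_layer()]
#' @export
rasterize_cell_center <- function(polygons, grid, category_attr = "category") {
  polygons <- validate_polygons(polygons, category_attr)
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (p in polygons) {
    cells <- bbox_cells(grid, poly_bbox(p))
    if (is.null(cells)) next
    cat_id <- poly_category(p, category_attr)
    ctr <- expand.grid(row = cells$rows, col = cells$cols)
    lon <- grid$origin_lon + (ctr$col - 0.5) * grid$cell_size_deg
    lat <- grid$origin_lat - (ctr$row - 0.5) * grid$cell_size_deg
    hit <- points_in_polygon(lon, lat, p)
    idx <- cbind(ctr$row, ctr$col)[hit, , drop = FALSE]
    empty <- is.na(vals[idx])  # earlier polygon wins on overlap
    vals[idx[empty, , drop = FALSE]] <- cat_id
  }
  raster_layer(grid, vals, semantics = "categorical")
}

#' Rasterize polygons by the maximum-area rule
#'
#' Each cell takes the category whose polygons cover the largest fraction
#' of the cell; cells with zero coverage are nodata. Per-category coverage
#' is the union over that category's polygons, estimated on an
#' `subsample x subsample` lattice of sub-points per cell (deterministic,
#' oracle-checkable). Ties go to the lowest category id. This is the rule
#' used for the protected-area layer.
#'
#' @inheritParams rasterize_cell_center
#' @param subsample per-cell sub-lattice size (>= 4; default 16)
#' @return categorical [raster_layer()]
#' @export
rasterize_max_area <- function(polygons, grid, subsample = 16L,
                               category_attr = "category") {
  subsample <- as.integer(subsample)
  if (is.na(subsample) || subsample < 4L) stop("subsample must be >= 4")
  polygons <- validate_polygons(polygons, category_attr)
  cats <- sort(unique(vapply(polygons, poly_category, 0L,
                             category_attr = category_attr)))
  best_count <- matrix(0L, grid$n_rows, grid$n_cols)
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  off <- (seq_len(subsample) - 0.5) / subsample  # fractions across the cell
  for (cat_id in cats) {  # ascending ids: strict > keeps lowest id on ties
    polys <- Filter(function(p) poly_category(p, category_attr) == cat_id,
                    polygons)
    bbs <- lapply(polys, poly_bbox)
    bb <- c(xmin = min(vapply(bbs, `[[`, 0, "xmin")),
            xmax = max(vapply(bbs, `[[`, 0, "xmax")),
            ymin = min(vapply(bbs, `[[`, 0, "ymin")),
            ymax = max(vapply(bbs, `[[`, 0, "ymax")))
    cells <- bbox_cells(grid, bb)
    if (is.null(cells)) next
    # sub-point lattice over the cell block
    nR <- length(cells$rows); nC <- length(cells$cols); s <- subsample
    sub_lon <- as.vector(vapply(cells$cols, function(cc)
      grid$origin_lon + (cc - 1 + off) * grid$cell_size_deg, numeric(s)))
    sub_lat <- as.vector(vapply(cells$rows, function(rr)
      grid$origin_lat - (rr - 1 + off) * grid$cell_size_deg, numeric(s)))
    lon <- rep(sub_lon, each = nR * s)
    lat <- rep(sub_lat, times = nC * s)
    covered <- rep(FALSE, length(lon))
    for (p in polys) covered <- covered | points_in_polygon(lon, lat, p)
    # fold sub-points back onto their cells (block is a full rectangle, so
    # sorted linear indices recover a column-major nR x nC count matrix)
    pt_row <- rep(rep(cells$rows, each = s), times = nC * s)
    pt_col <- rep(rep(cells$cols, each = s), each = nR * s)
    grp <- (pt_col - 1L) * grid$n_rows + pt_row
    cnt <- matrix(rowsum(as.integer(covered), group = grp)[, 1L], nrow = nR)
    win <- cnt > best_count[cells$rows, cells$cols, drop = FALSE]
    if (any(win)) {
      sub_best <- best_count[cells$rows, cells$cols, drop = FALSE]
      sub_vals <- vals[cells$rows, cells$cols, drop = FALSE]
      sub_best[win] <- cnt[win]
      sub_vals[win] <- cat_id
      best_count[cells$rows, cells$cols] <- sub_best
      vals[cells$rows, cells$cols] <- sub_vals
    }
  }
  raster_layer(grid, vals, semantics = "categorical")
}

WDPA_KEEP_STATUS <- c("designated", "inscribed", "established")
WDPA_KEEP_DOMAIN <- c("terrestrial", "coastal")

#' Filter protected-area polygons by WDPA attributes
#'
#' Keeps terrestrial and coastal reserves whose status is designated,
#' inscribed or established (case-insensitive). Polygons with a missing
#' status are excluded with a warning.
#'
#' @param polygons list of [geo_polygon()] with `status` and `domain`
#'   attributes
#' @return the retained subset
#' @export
filter_wdpa <- function(polygons) {
  keep <- vapply(polygons, function(p) {
    status <- p$attrs$status
    if (is.null(status) || is.na(status) || !nzchar(status)) {
      warning("protected-area polygon with missing status excluded")
      return(FALSE)
    }
    domain <- p$attrs$domain
    tolower(status) %in% WDPA_KEEP_STATUS &&
      !is.null(domain) && tolower(domain) %in% WDPA_KEEP_DOMAIN
  }, logical(1))
  polygons[keep]
}

#' Binary protected-area raster
#'
#' Rasterizes (pre-filtered) protected-area polygons by the maximum-area
#' rule against the single category "protected", then maps assigned cells
#' to 1 and everything else to 0 — the layer contract is strictly 0/1 with
#' no nodata.
#'
#' @param filtered_polygons polygons already passed through [filter_wdpa()]
#' @param grid a [grid_spec()]
#' @param subsample sub-lattice size, see [rasterize_max_area()]
#' @return binary [raster_layer()]
#' @export
to_binary_pa_raster <- function(filtered_polygons, grid, subsample = 16L) {
  polys <- lapply(filtered_polygons, function(p) {
    p$attrs$category <- 1L
    p
  })
  ras <- rasterize_max_area(polys, grid, subsample = subsample)
  vals <- layer_values(ras)
  vals[is.na(vals)] <- 0
  vals[vals != 0] <- 1
  raster_layer(grid, vals, semantics = "binary")
}
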