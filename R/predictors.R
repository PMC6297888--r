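#' Eco-geographic predictor stack
#'
#' The distribution models use 26 predictors on one shared grid: 19
#' bioclimatic variables plus solar radiation, wind speed and water vapor
#' pressure (WorldClim v2 roles), altitude (SRTM role), and slope and two
#' aspect components derived here from altitude. Layer names follow the
#' `wc2.0_bio_2.5m_NN` scheme of the source rasters.
#'
#' @name predictors
NULL

# Horn (1981) 8-neighbor gradients in m/m; returns list(gx east, gy north).
# Border cells and cells with a nodata neighbor are NA.
horn_gradients <- function(altitude) {
  g <- altitude$grid
  z <- layer_values(altitude)
  nr <- g$n_rows; nc <- g$n_cols
  if (nr < 2L || nc < 2L) stop("altitude must be at least 2 x 2 cells")
  shift <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- z[rs[ok_r], cs[ok_c]]
    out
  }
  nw <- shift(-1, -1); n_ <- shift(-1, 0); ne <- shift(-1, 1)
  w_ <- shift(0, -1);                      e_ <- shift(0, 1)
  sw <- shift(1, -1);  s_ <- shift(1, 0);  se <- shift(1, 1)

  lat_row <- g$origin_lat - (seq_len(nr) - 0.5) * g$cell_size_deg
  dx_m <- g$cell_size_deg * KM_PER_DEG * 1000 * cos(lat_row * pi / 180)
  dy_m <- g$cell_size_deg * KM_PER_DEG * 1000

  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * dx_m)  # recycles by row
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * dy_m)
  list(gx = gx, gy = gy)
}

#' Slope from altitude (Horn's method)
#'
#' Gradients use Horn's 8-neighbor weighting with lon/lat cell sizes
#' converted to meters at each row's latitude (dx scales with cos latitude).
#' Slope is `atan(sqrt(gx^2 + gy^2))` in degrees. Border cells and cells
#' adjacent to nodata become nodata.
#'
#' @param altitude continuous [raster_layer()] of elevation in meters
#' @return continuous [raster_layer()] of slope in degrees
#' @export
derive_slope <- function(altitude) {
  stopifnot(inherits(altitude, "raster_layer"))
  gr <- horn_gradients(altitude)
  slope <- atan(sqrt(gr$gx^2 + gr$gy^2)) * 180 / pi
  raster_layer(altitude$grid, slope, semantics = "continuous")
}

#' Aspect decomposed into north-south and east-west components
#'
#' Aspect (the downslope compass direction theta) is a circular variable;
#' to use it as linear predictors it is decomposed into
#' `aspect_ns = cos(theta)` and `aspect_ew = sin(theta)`, both in [-1, 1].
#' Flat cells (zero gradient) map to (0, 0) rather than nodata so they stay
#' modelable; wherever slope > 0 the components satisfy ns^2 + ew^2 = 1.
#'
#' @param altitude continuous [raster_layer()] of elevation in meters
#' @return list with continuous [raster_layer()] elements `ns` and `ew`
#' @export
derive_aspect_components <- function(altitude) {
  stopifnot(inherits(altitude, "raster_layer"))
  gr <- horn_gradients(altitude)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  # downslope unit vector: -(gx, gy) / |g|; compass ns = north comp, ew = east
  ns <- ifelse(mag > 0, -gr$gy / mag, 0)
  ew <- ifelse(mag > 0, -gr$gx / mag, 0)
  ns[is.na(mag)] <- NA_real_
  ew[is.na(mag)] <- NA_real_
  list(ns = raster_layer(altitude$grid, ns, semantics = "continuous"),
       ew = raster_layer(altitude$grid, ew, semantics = "continuous"))
}

predictor_layer_names <- function() sprintf("wc2.0_bio_2.5m_%02d", 1:26)

#' Assemble the 26-layer predictor stack
#'
#' Takes the 19 bioclim layers, the three additional climate surfaces and
#' altitude (all on one grid), derives slope and the two aspect components
#' from altitude, and returns the ordered 26-layer stack. Layers 1-19 are
#' tagged `"bioclim"`, 20-22 `"worldclim"`, 23 `"srtm"`, 24-26 `"derived"`.
#'
#' @param bioclim_layers list of exactly 19 [raster_layer()]
#' @param solar,wind,vapor,altitude [raster_layer()] on the same grid
#' @return an object of class `predictor_stack` with fields `grid` and
#'   `layers` (ordered list of `list(name, layer, source)`)
#' @export
assemble_stack <- function(bioclim_layers, solar, wind, vapor, altitude) {
  if (length(bioclim_layers) != 19L) {
    stop(sprintf("expected 19 bioclim layers, got %d", length(bioclim_layers)))
  }
  all_in <- c(bioclim_layers, list(solar, wind, vapor, altitude))
  grid <- altitude$grid
  for (lyr in all_in) {
    stopifnot(inherits(lyr, "raster_layer"))
    if (!same_grid(lyr$grid, grid)) stop("all input layers must share one grid")
  }
  slope <- derive_slope(altitude)
  aspect <- derive_aspect_components(altitude)
  layers_list <- c(bioclim_layers, list(solar, wind, vapor, altitude,
                                        slope, aspect$ns, aspect$ew))
  sources <- c(rep("bioclim", 19), rep("worldclim", 3), "srtm",
               rep("derived", 3))
  nm <- predictor_layer_names()
  layers <- lapply(seq_len(26L), function(i)
    list(name = nm[i], layer = layers_list[[i]], source = sources[i]))
  structure(list(grid = grid, layers = layers), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers on %d x %d grid\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Predictor values at cells
#'
#' Extracts the stack as a cells x 26 matrix for the given cell indices
#' (or all cells when `cells` is NULL), with nodata as `NA`.
#'
#' @param stack a `predictor_stack`
#' @param cells optional two-column (row, col) matrix
#' @return numeric matrix with one column per layer, named by layer
#' @export
stack_matrix <- function(stack, cells = NULL) {
  vals <- lapply(stack$layers, function(l) {
    v <- layer_values(l$layer)
    if (is.null(cells)) as.vector(v) else v[cells]
  })
  m <- do.call(cbind, vals)
  colnames(m) <- vapply(stack$layers, `[[`, "", "name")
  m
}

#' Write the predictor stack as ASCII grids
#' @param stack a `predictor_stack`
#' @param dir output directory (created if needed); one `<name>.asc` per layer
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in stack$layers) {
    write_ascii_grid(l$layer, file.path(dir, paste0(l$name, ".asc")))
  }
  invisible(dir)
}

#' Read a predictor stack written by [write_stack()]
#' @param dir directory containing the 22 input layers (bioclim 01-19,
#'   solar 20, wind 21, vapor 22, altitude 23); slope/aspect are re-derived
#' @return a `predictor_stack`
#' @export
read_stack <- function(dir) {
  nm <- predictor_layer_names()
  rd <- function(i) read_ascii_grid(file.path(dir, paste0(nm[i], ".asc")))
  assemble_stack(lapply(1:19, rd), rd(20), rd(21), rd(22), rd(23))
}
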