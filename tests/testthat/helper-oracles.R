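# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-implementations (winding numbers, double loops,
# finite differences) that never call the package code paths they check.

# winding-number point-in-polygon (non-zero rule; agrees with even-odd on
# simple polygons). Boundary points are resolved as inside, matching the
# package convention.
oracle_point_in_polygon <- function(lon, lat, ring) {
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    j <- if (i == n) 1L else i + 1L
    x2 <- ring[j, 1]; y2 <- ring[j, 2]
    # boundary check
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    dot <- (lon - x1) * (x2 - x1) + (lat - y1) * (y2 - y1)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (abs(cross) <= 1e-12 * max(1, abs(lon), abs(lat)) &&
        dot >= -1e-12 && dot <= len2 + 1e-12) return(TRUE)
    if (y1 <= lat) {
      if (y2 > lat && cross > 0) wn <- wn + 1
    } else {
      if (y2 <= lat && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# random convex polygon: convex hull of random points
random_convex_polygon <- function(n = 8, lon_range = c(-5, 5),
                                  lat_range = c(-5, 5)) {
  pts <- cbind(runif(n, lon_range[1], lon_range[2]),
               runif(n, lat_range[1], lat_range[2]))
  hull <- chull(pts)
  geo_polygon(pts[hull, , drop = FALSE])
}

# brute-force CA50: double loop over cells x points
oracle_ca50 <- function(points, grid, mask, radius_km = 50) {
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  land <- plantgap:::layer_values(mask)
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      if (is.na(land[r, c]) || land[r, c] != 1) next
      ctr <- cell_center(grid, r, c)
      hit <- FALSE
      for (k in seq_len(nrow(points))) {
        if (haversine_km(ctr[1], ctr[2], points$lon[k], points$lat[k]) <= radius_km) {
          hit <- TRUE; break
        }
      }
      vals[r, c] <- as.numeric(hit)
    }
  }
  vals
}

# sub-point counting oracle for the maximum-area rule: per cell, count the
# s x s sub-points covered by any polygon of each category (winding oracle)
oracle_max_area <- function(polygons, grid, s = 32L) {
  cats <- sort(unique(vapply(polygons, function(p) as.integer(p$attrs$category), 0L)))
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  off <- (seq_len(s) - 0.5) / s
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      best_cat <- NA_real_; best_n <- 0L
      for (cat_id in cats) {
        n_in <- 0L
        for (fy in off) {
          lat <- grid$origin_lat - (r - 1 + fy) * grid$cell_size_deg
          for (fx in off) {
            lon <- grid$origin_lon + (c - 1 + fx) * grid$cell_size_deg
            for (p in polygons) {
              if (as.integer(p$attrs$category) != cat_id) next
              if (oracle_point_in_polygon(lon, lat, p$exterior)) {
                n_in <- n_in + 1L; break
              }
            }
          }
        }
        if (n_in > best_n) { best_n <- n_in; best_cat <- cat_id }
      }
      if (best_n > 0L) vals[r, c] <- best_cat
    }
  }
  vals
}

# central finite-difference slope oracle reproducing Horn weights
oracle_slope_deg <- function(altitude) {
  g <- altitude$grid
  z <- plantgap:::layer_values(altitude)
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  km_deg <- 6371 * pi / 180
  for (r in 2:(g$n_rows - 1)) {
    lat <- g$origin_lat - (r - 0.5) * g$cell_size_deg
    dx <- g$cell_size_deg * km_deg * 1000 * cos(lat * pi / 180)
    dy <- g$cell_size_deg * km_deg * 1000
    for (c in 2:(g$n_cols - 1)) {
      zz <- z[(r - 1):(r + 1), (c - 1):(c + 1)]
      if (anyNA(zz)) next
      gx <- ((zz[1, 3] + 2 * zz[2, 3] + zz[3, 3]) -
               (zz[1, 1] + 2 * zz[2, 1] + zz[3, 1])) / (8 * dx)
      gy <- ((zz[1, 1] + 2 * zz[1, 2] + zz[1, 3]) -
               (zz[3, 1] + 2 * zz[3, 2] + zz[3, 3])) / (8 * dy)
      out[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    }
  }
  out
}
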