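#' Synthetic world generator
#'
#' Generates a fully self-consistent desk-scale world — grid, land mask
#' with ocean margin and an inland lake, rectangular countries, ecoregion
#' bands, protected-area rectangles, 22 smooth climate surfaces plus a
#' deterministic altitude surface, and species with Gaussian niches sampled
#' into G/H occurrence records including deliberately dirty records — with
#' full ground-truth bookkeeping, so every pipeline stage and every score
#' is checkable without downloads. Countries, ecoregions and protected
#' areas are axis-aligned rectangles so areas and memberships have closed
#' forms; climate layers are independent smooth fields (realism is traded
#' for checkability).
#'
#' @name synthgen
NULL

#' Synthetic world configuration
#'
#' Defaults describe a 60 x 60 grid of 0.5-degree cells centered on the
#' equator, 4 countries, 5 ecoregion bands, a protected-area target of 25%
#' of the land, and 8 modeled species with 15 G + 35 H records each, of
#' which 3 are planted in water, 2 are pre-1950 and 2 sit in a non-native
#' country. Identical seeds produce identical worlds.
#'
#' @param n_rows,n_cols,cell_size_deg,origin_lon,origin_lat grid geometry
#' @param n_countries number of rectangular countries (vertical strips)
#' @param n_ecoregions number of ecoregion bands (horizontal strips)
#' @param pa_fraction target protected fraction of the land block in [0, 1]
#' @param n_species number of modeled (selected) species
#' @param n_decoy_species species that fail the use/cultivation filter
#' @param n_g,n_h clean germplasm / reference records per species
#' @param n_water,n_old,n_nonnative planted violations per species (drawn
#'   from the H records; their sum must be <= `n_h`)
#' @param n_g_nocoord,n_h_nocoord records without coordinates per species
#' @param niche_predictor predictor layer the species niches live on
#' @param niche_breadth Gaussian niche breadth (predictor units)
#' @param noise_sd sd of the climate-surface noise
#' @param seed integer RNG seed
#' @return list of class `world_config`
#' @export
world_config <- function(n_rows = 60L, n_cols = 60L, cell_size_deg = 0.5,
                         origin_lon = -15, origin_lat = 15,
                         n_countries = 4L, n_ecoregions = 5L,
                         pa_fraction = 0.25,
                         n_species = 8L, n_decoy_species = 2L,
                         n_g = 15L, n_h = 35L,
                         n_water = 3L, n_old = 2L, n_nonnative = 2L,
                         n_g_nocoord = 0L, n_h_nocoord = 0L,
                         niche_predictor = "wc2.0_bio_2.5m_01",
                         niche_breadth = 1.5, noise_sd = 0.3,
                         seed = 42L) {
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              cell_size_deg = cell_size_deg, origin_lon = origin_lon,
              origin_lat = origin_lat, n_countries = as.integer(n_countries),
              n_ecoregions = as.integer(n_ecoregions),
              pa_fraction = pa_fraction, n_species = as.integer(n_species),
              n_decoy_species = as.integer(n_decoy_species),
              n_g = as.integer(n_g), n_h = as.integer(n_h),
              n_water = as.integer(n_water), n_old = as.integer(n_old),
              n_nonnative = as.integer(n_nonnative),
              n_g_nocoord = as.integer(n_g_nocoord),
              n_h_nocoord = as.integer(n_h_nocoord),
              niche_predictor = niche_predictor,
              niche_breadth = niche_breadth, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$pa_fraction < 0 || cfg$pa_fraction > 1) stop("pa_fraction must be in [0, 1]")
  if (cfg$n_water + cfg$n_old + cfg$n_nonnative > cfg$n_h) {
    stop("planted violations exceed the number of H records")
  }
  if (cfg$n_rows < 12L || cfg$n_cols < 12L) stop("grid too small for the world layout")
  if (cfg$n_countries < 2L) stop("need at least 2 countries (non-native contamination)")
  structure(cfg, class = "world_config")
}

# margin (in cells) of ocean around the land block
WORLD_OCEAN_MARGIN <- 3L
# inland lake: square of cells at the center of the grid
WORLD_LAKE_CELLS <- 4L

synthetic_iso3 <- function(n) vapply(seq_len(n), function(i)
  strrep(LETTERS[i], 3L), "")

# closed-form world geometry shared by generator and tests
world_layout <- function(cfg) {
  g <- grid_spec(cell_size_deg = cfg$cell_size_deg,
                 origin_lon = cfg$origin_lon, origin_lat = cfg$origin_lat,
                 n_rows = cfg$n_rows, n_cols = cfg$n_cols)
  m <- WORLD_OCEAN_MARGIN
  land_rows <- (m + 1L):(cfg$n_rows - m)
  land_cols <- (m + 1L):(cfg$n_cols - m)
  lk <- WORLD_LAKE_CELLS
  lake_rows <- (cfg$n_rows %/% 2L - lk %/% 2L + 1L):(cfg$n_rows %/% 2L + lk %/% 2L)
  lake_cols <- (cfg$n_cols %/% 2L - lk %/% 2L + 1L):(cfg$n_cols %/% 2L + lk %/% 2L)
  cs <- cfg$cell_size_deg
  deg <- function(rows, cols) c(
    lon_min = cfg$origin_lon + (min(cols) - 1L) * cs,
    lon_max = cfg$origin_lon + max(cols) * cs,
    lat_min = cfg$origin_lat - max(rows) * cs,
    lat_max = cfg$origin_lat - (min(rows) - 1L) * cs)
  list(grid = g, land_rows = land_rows, land_cols = land_cols,
       lake_rows = lake_rows, lake_cols = lake_cols,
       land_deg = deg(land_rows, land_cols),
       lake_deg = deg(lake_rows, lake_cols))
}

smooth_field <- function(grid, a, b, c1, c2, base, noise_sd) {
  rows <- seq_len(grid$n_rows); cols <- seq_len(grid$n_cols)
  lat <- grid$origin_lat - (rows - 0.5) * grid$cell_size_deg
  lon <- grid$origin_lon + (cols - 0.5) * grid$cell_size_deg
  field <- base + outer(a * lat, b * lon, `+`) +
    c1 * outer(sin(lat / 4), cos(lon / 4)) +
    c2 * outer(cos(lat / 7), sin(lon / 7))
  field + matrix(stats::rnorm(length(field), sd = noise_sd),
                 grid$n_rows, grid$n_cols)
}

#' Sample occurrence points for a Gaussian niche
#'
#' Draws cells (with replacement) with probability proportional to
#' `exp(-(x - optimum)^2 / (2 * breadth^2))` of the niche predictor over
#' the eligible land cells, then jitters each point uniformly within its
#' cell. The first `n_g` draws become G records, the rest H.
#'
#' @param niche list with `predictor`, `optimum`, `breadth`
#' @param stack a `predictor_stack`
#' @param mask binary [raster_layer()]; sampling is restricted to mask = 1
#' @param n_g,n_h number of G and H records
#' @param seed RNG seed
#' @param eligible optional logical matrix further restricting cells
#' @return data frame with `lon`, `lat`, `row`, `col`, `record_type`
#' @export
sample_species_occurrences <- function(niche, stack, mask, n_g, n_h, seed,
                                       eligible = NULL) {
  pred_i <- match(niche$predictor, vapply(stack$layers, `[[`, "", "name"))
  if (is.na(pred_i)) stop("niche references unknown predictor: ", niche$predictor)
  x <- layer_values(stack$layers[[pred_i]]$layer)
  ok <- layer_values(mask) == 1 & !is.na(x)
  if (!is.null(eligible)) ok <- ok & eligible
  cells <- which(ok)
  if (length(cells) == 0L) stop("no eligible land cells to sample from")
  w <- exp(-(x[cells] - niche$optimum)^2 / (2 * niche$breadth^2))
  n <- n_g + n_h
  with_seed(seed, {
    drawn <- sample(cells, n, replace = TRUE, prob = w)
    row <- ((drawn - 1L) %% nrow(x)) + 1L
    col <- ((drawn - 1L) %/% nrow(x)) + 1L
    ctr <- cell_center(mask$grid, row, col)
    jit <- (matrix(stats::runif(2L * n), ncol = 2L) - 0.5) *
      0.9 * mask$grid$cell_size_deg
    data.frame(lon = ctr[, "lon"] + jit[, 1L], lat = ctr[, "lat"] + jit[, 2L],
               row = row, col = col,
               record_type = rep(c("G", "H"), c(n_g, n_h)),
               stringsAsFactors = FALSE)
  })
}

#' Generate the synthetic world
#'
#' Emits every input contract of the pipeline, in memory (and on disk when
#' `out_dir` is given): WEP-style names/uses/distribution tables, one
#' occurrence data frame per species with planted violations, the 26-layer
#' predictor stack, land mask, country / ecoregion / protected-area polygon
#' layers, an M49-style classification table — plus a `ground_truth` list
#' recording niches, per-record violation labels, expected post-scrub
#' counts, native-country assignments and the protected/ecoregion layouts.
#'
#' @param config a [world_config()]
#' @param out_dir optional directory; when given, all contracts are written
#'   as CSV / ASCII-grid / GeoJSON files
#' @return list of class `synthetic_world`; see Details
#' @export
generate_world <- function(config = world_config(), out_dir = NULL) {
  stopifnot(inherits(config, "world_config"))
  lay <- world_layout(config)
  g <- lay$grid
  if (config$n_countries > length(lay$land_cols)) {
    stop("more countries than land columns")
  }
  if (config$n_ecoregions > length(lay$land_rows)) {
    stop("more ecoregions than land rows")
  }

  # land mask: land block minus the lake
  mvals <- matrix(0, g$n_rows, g$n_cols)
  mvals[lay$land_rows, lay$land_cols] <- 1
  mvals[lay$lake_rows, lay$lake_cols] <- 0
  mask <- raster_layer(g, mvals, "binary")

  # countries: vertical strips of the land block
  iso <- synthetic_iso3(config$n_countries)
  breaks <- floor(seq(0L, length(lay$land_cols), length.out = config$n_countries + 1L))
  country_cols <- lapply(seq_len(config$n_countries), function(i)
    lay$land_cols[(breaks[i] + 1L):breaks[i + 1L]])
  cs <- g$cell_size_deg
  country_polys <- lapply(seq_len(config$n_countries), function(i) {
    cc <- country_cols[[i]]
    rect_polygon(g$origin_lon + (min(cc) - 1L) * cs,
                 g$origin_lon + max(cc) * cs,
                 lay$land_deg[["lat_min"]], lay$land_deg[["lat_max"]],
                 attrs = list(iso3 = iso[i]))
  })
  country_of_col <- integer(g$n_cols)
  for (i in seq_along(country_cols)) country_of_col[country_cols[[i]]] <- i

  # ecoregions: horizontal bands of the land block
  ebreaks <- floor(seq(0L, length(lay$land_rows), length.out = config$n_ecoregions + 1L))
  eco_rows <- lapply(seq_len(config$n_ecoregions), function(i)
    lay$land_rows[(ebreaks[i] + 1L):ebreaks[i + 1L]])
  ecoregion_polys <- lapply(seq_len(config$n_ecoregions), function(i) {
    rr <- eco_rows[[i]]
    rect_polygon(lay$land_deg[["lon_min"]], lay$land_deg[["lon_max"]],
                 g$origin_lat - max(rr) * cs, g$origin_lat - (min(rr) - 1L) * cs,
                 attrs = list(category = i))
  })
  eco_vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  for (i in seq_along(eco_rows)) eco_vals[eco_rows[[i]], lay$land_cols] <- i
  ecoregions <- raster_layer(g, eco_vals, "categorical")

  # protected areas: a band at the southern edge of the land block covering
  # pa_fraction of the land rows (full map when pa_fraction = 1), plus
  # decoy polygons that the WDPA filter must drop
  pa_polys <- list()
  n_pa_rows <- round(config$pa_fraction * length(lay$land_rows))
  if (config$pa_fraction >= 1) {
    pa_polys <- list(rect_polygon(g$origin_lon, g$origin_lon + g$n_cols * cs,
                                  g$origin_lat - g$n_rows * cs, g$origin_lat,
                                  attrs = list(status = "designated",
                                               domain = "terrestrial",
                                               category = 1L)))
    pa_rows <- seq_len(g$n_rows)
  } else if (n_pa_rows > 0L) {
    pa_rows <- lay$land_rows[(length(lay$land_rows) - n_pa_rows + 1L):length(lay$land_rows)]
    pa_polys <- list(rect_polygon(lay$land_deg[["lon_min"]],
                                  lay$land_deg[["lon_max"]],
                                  g$origin_lat - max(pa_rows) * cs,
                                  g$origin_lat - (min(pa_rows) - 1L) * cs,
                                  attrs = list(status = "designated",
                                               domain = "terrestrial",
                                               category = 1L)))
  } else pa_rows <- integer(0)
  decoys <- list(
    rect_polygon(g$origin_lon, g$origin_lon + 2 * cs,
                 g$origin_lat - 2 * cs, g$origin_lat,
                 attrs = list(status = "proposed", domain = "terrestrial",
                              category = 1L)),
    rect_polygon(g$origin_lon, g$origin_lon + 2 * cs,
                 g$origin_lat - g$n_rows * cs,
                 g$origin_lat - (g$n_rows - 2L) * cs,
                 attrs = list(status = "designated", domain = "marine",
                              category = 1L)))
  pa_all_polys <- c(pa_polys, decoys)
  pa_vals <- matrix(0, g$n_rows, g$n_cols)
  if (length(pa_rows)) {
    if (config$pa_fraction >= 1) pa_vals[] <- 1
    else pa_vals[pa_rows, lay$land_cols] <- 1
  }
  pa <- raster_layer(g, pa_vals, "binary")

  # predictor stack: 22 seeded smooth fields + deterministic altitude
  stack <- with_seed(config$seed, {
    bio <- vector("list", 19L)
    # bioclim 01 is the niche axis: fixed coefficients (known form) but the
    # same smooth-field family as the other layers, so its level sets are
    # curvy regions no other predictor reproduces (niche identifiability)
    bio[[1L]] <- raster_layer(g, smooth_field(g, 0.25, 0, 2.5, 1.5, 24,
                                              config$noise_sd),
                              "continuous")
    for (i in 2:19) {
      co <- stats::runif(5L, -1, 1)
      bio[[i]] <- raster_layer(g, smooth_field(g, co[1L] * 0.4, co[2L] * 0.4,
                                               co[3L] * 3, co[4L] * 3,
                                               20 + 10 * co[5L],
                                               config$noise_sd),
                               "continuous")
    }
    extra <- lapply(1:3, function(i) {
      co <- stats::runif(5L, -1, 1)
      raster_layer(g, smooth_field(g, co[1L] * 0.3, co[2L] * 0.3,
                                   co[3L] * 2, co[4L] * 2, 10 + 5 * co[5L],
                                   config$noise_sd), "continuous")
    })
    lat <- g$origin_lat - (seq_len(g$n_rows) - 0.5) * g$cell_size_deg
    lonm <- g$origin_lon + (seq_len(g$n_cols) - 0.5) * cs
    alt <- 500 + 300 * outer(cos(lat / 4), sin(lonm / 4))
    assemble_stack(bio, extra[[1L]], extra[[2L]], extra[[3L]],
                   raster_layer(g, alt, "continuous"))
  })

  # species: niches on the niche predictor, native ranges = 2 countries
  pred_names <- vapply(stack$layers, `[[`, "", "name")
  niche_x <- layer_values(stack$layers[[match(config$niche_predictor,
                                              pred_names)]]$layer)
  land_lin <- which(mvals == 1)
  sp_ids <- sprintf("SP%04d", seq_len(config$n_species))
  use_pool <- c("food", "medicine", "forage", "fiber", "fuel",
                "environmental", "gene_source")
  species <- with_seed(config$seed + 1L, lapply(seq_len(config$n_species),
                                                function(i) {
    native_idx <- sort(sample(config$n_countries, 2L))
    opt <- stats::runif(1L, stats::quantile(niche_x[land_lin], 0.2),
                        stats::quantile(niche_x[land_lin], 0.8))
    list(species_id = sp_ids[i],
         name = sprintf("Synthuseful species%02d", i),
         author = "Synth.", uses = sample(use_pool, sample(1:3, 1L)),
         native_idx = native_idx, native_iso3 = iso[native_idx],
         niche = list(predictor = config$niche_predictor, optimum = opt,
                      breadth = config$niche_breadth))
  }))

  # occurrence records with planted violations
  ocean_lin <- which(mvals == 0)
  occurrences <- list()
  truth_records <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    native_cols <- unlist(country_cols[sp$native_idx])
    elig <- matrix(FALSE, g$n_rows, g$n_cols)
    elig[, native_cols] <- TRUE
    pts <- sample_species_occurrences(sp$niche, stack, mask,
                                      config$n_g, config$n_h,
                                      seed = config$seed + 100L + i,
                                      eligible = elig)
    n <- nrow(pts)
    rec <- with_seed(config$seed + 200L + i, data.frame(
      species_id = sp$species_id, lon = pts$lon, lat = pts$lat,
      iso3 = iso[country_of_col[pts$col]],
      year = sample(1960:2015, n, replace = TRUE),
      record_type = pts$record_type, native_status = "N",
      stringsAsFactors = FALSE))
    label <- rep("clean", n)
    # corrupt trailing H records: water, then pre-1950, then non-native
    h_idx <- which(rec$record_type == "H")
    bad <- rev(h_idx)[seq_len(config$n_water + config$n_old + config$n_nonnative)]
    corrupt <- with_seed(config$seed + 300L + i, {
      w_i <- bad[seq_len(config$n_water)]
      o_i <- bad[config$n_water + seq_len(config$n_old)]
      nn_i <- bad[config$n_water + config$n_old + seq_len(config$n_nonnative)]
      if (length(w_i)) {
        wc <- sample(ocean_lin, length(w_i))
        ctr <- cell_center(g, ((wc - 1L) %% g$n_rows) + 1L,
                           ((wc - 1L) %/% g$n_rows) + 1L)
        rec$lon[w_i] <- ctr[, "lon"]; rec$lat[w_i] <- ctr[, "lat"]
      }
      if (length(o_i)) rec$year[o_i] <- sample(1900:1949, length(o_i),
                                               replace = TRUE)
      if (length(nn_i)) {
        foreign <- setdiff(seq_len(config$n_countries), sp$native_idx)
        fc <- sample(rep(foreign, 2L), length(nn_i), replace = TRUE)
        for (k in seq_along(nn_i)) {
          cols_k <- country_cols[[fc[k]]]
          repeat {  # avoid the lake: the planted violation must be dry land
            cell_col <- cols_k[sample.int(length(cols_k), 1L)]
            cell_row <- lay$land_rows[sample.int(length(lay$land_rows), 1L)]
            if (mvals[cell_row, cell_col] == 1) break
          }
          ctr <- cell_center(g, cell_row, cell_col)
          rec$lon[nn_i[k]] <- ctr[, "lon"]; rec$lat[nn_i[k]] <- ctr[, "lat"]
          rec$iso3[nn_i[k]] <- iso[fc[k]]
          rec$native_status[nn_i[k]] <- "I"
        }
      }
      list(rec = rec, w_i = w_i, o_i = o_i, nn_i = nn_i)
    })
    rec <- corrupt$rec
    label[corrupt$w_i] <- "water"
    label[corrupt$o_i] <- "too-old"
    label[corrupt$nn_i] <- "non-native"
    # records without coordinates (kept by scrubbing, unusable for SDM)
    if (config$n_g_nocoord + config$n_h_nocoord > 0L) {
      extra <- data.frame(
        species_id = sp$species_id, lon = NA_real_, lat = NA_real_,
        iso3 = sp$native_iso3[1L], year = 1990L,
        record_type = rep(c("G", "H"),
                          c(config$n_g_nocoord, config$n_h_nocoord)),
        native_status = "N", stringsAsFactors = FALSE)
      rec <- rbind(rec, extra)
      label <- c(label, rep("clean", nrow(extra)))
    }
    occurrences[[sp$species_id]] <- rec
    truth_records[[sp$species_id]] <- list(
      labels = label,
      expected_kept = sum(label == "clean"),
      expected_rejected = table(factor(label[label != "clean"],
                                       levels = c("water", "non-native",
                                                  "too-old"))))
  }

  # WEP-style tables (selected species + decoys that must be filtered out)
  decoy_ids <- if (config$n_decoy_species > 0L)
    sprintf("DX%04d", seq_len(config$n_decoy_species)) else character(0)
  names_df <- data.frame(
    species_id = c(sp_ids, decoy_ids),
    name = c(vapply(species, `[[`, "", "name"),
             sprintf("Synthdecoy species%02d", seq_along(decoy_ids))),
    author = "Synth.",
    strictly_cultivated = c(rep(FALSE, length(sp_ids)),
                            rep(c(FALSE, TRUE), length.out = length(decoy_ids))),
    stringsAsFactors = FALSE)
  uses_df <- do.call(rbind, c(
    lapply(species, function(sp)
      data.frame(species_id = sp$species_id, use = sp$uses,
                 stringsAsFactors = FALSE)),
    lapply(seq_along(decoy_ids), function(i)
      data.frame(species_id = decoy_ids[i],
                 use = if (i %% 2L == 1L) "ornamental" else "food",
                 stringsAsFactors = FALSE))))
  dist_df <- do.call(rbind, lapply(species, function(sp) {
    sid <- sp$species_id
    nn <- unique(occurrences[[sid]]$iso3[occurrences[[sid]]$native_status == "I"])
    rbind(data.frame(species_id = sid, iso3 = sp$native_iso3, status = "N",
                     stringsAsFactors = FALSE),
          if (length(nn)) data.frame(species_id = sid, iso3 = nn,
                                     status = "I", stringsAsFactors = FALSE))
  }))
  if (length(decoy_ids)) {
    dist_df <- rbind(dist_df,
                     data.frame(species_id = decoy_ids, iso3 = iso[1L],
                                status = "N", stringsAsFactors = FALSE))
  }

  # M49-style classification: countries paired into sub-regions, which are
  # paired into regions
  sub_idx <- ceiling(seq_len(config$n_countries) / 2)
  reg_idx <- ceiling(sub_idx / 2)
  m49 <- data.frame(iso3 = iso,
                    country = paste("Country", iso),
                    sub_region_code = paste0("s", sub_idx),
                    sub_region = paste("Sub-region", sub_idx),
                    region_code = paste0("r", reg_idx),
                    region = paste("Region", reg_idx),
                    stringsAsFactors = FALSE)

  world <- structure(list(
    config = config, grid = g, mask = mask, stack = stack,
    country_polygons = country_polys, ecoregion_polygons = ecoregion_polys,
    pa_polygons = pa_all_polys,
    ecoregions = ecoregions, pa = pa,
    names_table = names_df, uses_table = uses_df,
    distributions_table = dist_df, m49 = m49,
    occurrences = occurrences,
    ground_truth = list(
      species = species, selected_ids = sp_ids, decoy_ids = decoy_ids,
      records = truth_records,
      native_iso3 = stats::setNames(lapply(species, `[[`, "native_iso3"),
                                    sp_ids),
      land_cells = length(land_lin),
      pa_rows = pa_rows, eco_rows = eco_rows,
      country_cols = stats::setNames(country_cols, iso))),
    class = "synthetic_world")
  if (!is.null(out_dir)) write_world(world, out_dir)
  world
}

#' Write a synthetic world to disk
#'
#' Emits the exact file layouts the pipeline consumes: `names.csv`,
#' `uses.csv`, `distributions.csv`, `m49.csv`, `occurrences/<id>.csv`,
#' `mask.asc`, `ecoregions.asc`, `pa.asc`, `predictors/<layer>.asc`, and
#' `countries.geojson` / `ecoregions.geojson` / `pa.geojson`.
#'
#' @param world a `synthetic_world`
#' @param dir output directory (created)
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE)
  wcsv(world$names_table, "names.csv")
  wcsv(world$uses_table, "uses.csv")
  wcsv(world$distributions_table, "distributions.csv")
  wcsv(world$m49, "m49.csv")
  occ_dir <- file.path(dir, "occurrences")
  dir.create(occ_dir, showWarnings = FALSE)
  for (sid in names(world$occurrences)) {
    utils::write.csv(world$occurrences[[sid]],
                     file.path(occ_dir, paste0(sid, ".csv")),
                     row.names = FALSE)
  }
  write_ascii_grid(world$mask, file.path(dir, "mask.asc"))
  write_ascii_grid(world$ecoregions, file.path(dir, "ecoregions.asc"))
  write_ascii_grid(world$pa, file.path(dir, "pa.asc"))
  write_stack(world$stack, file.path(dir, "predictors"))
  write_polygons_geojson(world$country_polygons,
                         file.path(dir, "countries.geojson"))
  write_polygons_geojson(world$ecoregion_polygons,
                         file.path(dir, "ecoregions.geojson"))
  write_polygons_geojson(world$pa_polygons, file.path(dir, "pa.geojson"))
  invisible(dir)
}
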