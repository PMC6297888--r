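#' Conservation representativeness scores
#'
#' Per-species conservation is scored on three axes, each 0-100, computed
#' both ex situ (genebank holdings) and in situ (protected areas):
#'
#' * SRS (sampling): ex situ, the share of records that are germplasm
#'   accessions, `100 * G / (G + H)`; in situ, the share of georeferenced
#'   occurrences falling in protected-area cells.
#' * GRS (geographic): the area of the species' distribution covered — by
#'   the 50-km buffer around G records (ex situ) or by protected areas
#'   (in situ) — as a percentage of the distribution's area, weighted by
#'   true cell area.
#' * ERS (ecological): the share of the distribution's ecoregions that the
#'   covered part touches.
#'
#' FCS is the unweighted mean of the three scores on each axis, and the
#' combined FCS the mean of the two FCS values; the combined score maps to
#' a priority category (< 25 urgent, 25-50 high, 50-75 medium, >= 75 low).
#' Any score with an empty denominator is defined as 0 (conservative: no
#' credit for absent data).
#'
#' @name conservation
NULL

#' Per-row cell areas of a lon/lat grid
#'
#' Spherical approximation: a cell at latitude phi has area
#' `(cell_size_deg * 111.1949 km)^2 * cos(phi)`, adequate at the pipeline's
#' resolutions. Areas are constant within a row.
#'
#' @param grid a [grid_spec()]
#' @return object of class `cell_area_model`: `grid` plus `row_area_km2`
#' @export
cell_area_model <- function(grid) {
  lat <- grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size_deg
  area <- (grid$cell_size_deg * KM_PER_DEG)^2 * cos(lat * pi / 180)
  if (any(area <= 0)) stop("grid rows at or beyond the poles have non-positive area")
  structure(list(grid = grid, row_area_km2 = area), class = "cell_area_model")
}

# total area (km2) of cells where binary layer == 1
masked_area <- function(layer, areas) {
  stopifnot(same_grid(layer$grid, areas$grid))
  v <- layer_values(layer) == 1
  v[is.na(v)] <- FALSE
  sum(rowSums(v) * areas$row_area_km2)
}

binary_and <- function(a, b) {
  stopifnot(same_grid(a$grid, b$grid))
  va <- layer_values(a) == 1; va[is.na(va)] <- FALSE
  vb <- layer_values(b) == 1; vb[is.na(vb)] <- FALSE
  raster_layer(a$grid, (va & vb) * 1, "binary")
}

# distinct ecoregion ids over cells where `where` == 1
ecoregions_present <- function(ecoregions, where) {
  stopifnot(same_grid(ecoregions$grid, where$grid))
  w <- layer_values(where) == 1
  w[is.na(w)] <- FALSE
  ids <- layer_values(ecoregions)[w]
  sort(unique(ids[!is.na(ids)]))
}

#' Ex situ sampling representativeness (SRS ex situ)
#'
#' @param counts one-row counts frame from [summarize_occurrences()]
#' @return percentage in [0, 100]; 0 when the species has no records
#' @export
srs_ex <- function(counts) {
  tot <- counts$g_records + counts$h_records
  if (tot == 0L) return(0)
  100 * counts$g_records / tot
}

#' Ex situ geographic representativeness (GRS ex situ)
#'
#' Area of the G-record CA50 buffer inside the distribution, as a
#' percentage of the distribution's area (area-weighted by latitude).
#'
#' @param g_buffer binary [raster_layer()] from [ca50()] on G records only
#'   (or `NULL` when the species has no georeferenced G records)
#' @param distribution binary [raster_layer()] (validated SDM presence or
#'   all-records CA50)
#' @param areas a [cell_area_model()]
#' @return percentage in [0, 100]
#' @export
grs_ex <- function(g_buffer, distribution, areas) {
  denom <- masked_area(distribution, areas)
  if (denom == 0) return(0)
  if (is.null(g_buffer)) return(0)
  num <- masked_area(binary_and(g_buffer, distribution), areas)
  min(100, 100 * num / denom)
}

#' Ex situ ecological representativeness (ERS ex situ)
#'
#' Share of the distribution's ecoregions touched by the G-record buffer.
#'
#' @inheritParams grs_ex
#' @param ecoregions categorical [raster_layer()]
#' @return percentage in [0, 100]
#' @export
ers_ex <- function(g_buffer, distribution, ecoregions) {
  in_dist <- ecoregions_present(ecoregions, distribution)
  if (length(in_dist) == 0L) return(0)
  if (is.null(g_buffer)) return(0)
  in_buf <- ecoregions_present(ecoregions, binary_and(g_buffer, distribution))
  100 * length(intersect(in_buf, in_dist)) / length(in_dist)
}

#' In situ scores (SRS, GRS, ERS)
#'
#' GRS in situ is the protected share of the distribution's area; ERS in
#' situ the protected share of its ecoregions; SRS in situ the share of
#' georeferenced occurrences lying in protected-area cells.
#'
#' @param distribution binary [raster_layer()]
#' @param pa binary protected-area [raster_layer()] (0/1 everywhere)
#' @param ecoregions categorical [raster_layer()]
#' @param occurrences scrubbed occurrence data frame (georeferenced rows
#'   used for SRS in situ)
#' @param areas a [cell_area_model()]
#' @return named numeric vector `c(srs_in, grs_in, ers_in)`
#' @export
insitu_scores <- function(distribution, pa, ecoregions, occurrences, areas) {
  stopifnot(same_grid(distribution$grid, pa$grid))
  denom_area <- masked_area(distribution, areas)
  protected <- binary_and(distribution, pa)
  grs_in <- if (denom_area == 0) 0 else
    min(100, 100 * masked_area(protected, areas) / denom_area)
  eco_dist <- ecoregions_present(ecoregions, distribution)
  ers_in <- if (length(eco_dist) == 0L) 0 else
    100 * length(intersect(ecoregions_present(ecoregions, protected),
                           eco_dist)) / length(eco_dist)
  geo <- occurrences[!is.na(occurrences$lon) & !is.na(occurrences$lat), ,
                     drop = FALSE]
  srs_in <- 0
  if (nrow(geo) > 0L) {
    idx <- cell_index(pa$grid, geo$lon, geo$lat)
    on_grid <- !is.na(idx[, "row"])
    pav <- layer_values(pa)
    in_pa <- rep(FALSE, nrow(geo))
    in_pa[on_grid] <- pav[idx[on_grid, , drop = FALSE]] == 1
    in_pa[is.na(in_pa)] <- FALSE
    srs_in <- 100 * sum(in_pa) / nrow(geo)
  }
  c(srs_in = srs_in, grs_in = grs_in, ers_in = unname(ers_in))
}

#' Combine component scores and assign a priority category
#'
#' FCS ex situ and in situ are the unweighted means of their three
#' components; the combined FCS is the mean of the two. Categories:
#' combined FCS < 25 urgent, [25, 50) high, [50, 75) medium, >= 75
#' low_priority.
#'
#' @param species_id species identifier
#' @param srs_ex,grs_ex,ers_ex,srs_in,grs_in,ers_in component scores in
#'   [0, 100]
#' @return one-row data frame of class `conservation_scores` with all nine
#'   scores and the category
#' @export
combine_and_categorize <- function(species_id, srs_ex, grs_ex, ers_ex,
                                   srs_in, grs_in, ers_in) {
  comp <- c(srs_ex, grs_ex, ers_ex, srs_in, grs_in, ers_in)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 100)) {
    stop("component scores must lie in [0, 100]")
  }
  fcs_ex <- mean(c(srs_ex, grs_ex, ers_ex))
  fcs_in <- mean(c(srs_in, grs_in, ers_in))
  fcs_combined <- mean(c(fcs_ex, fcs_in))
  category <- if (fcs_combined < 25) "urgent"
  else if (fcs_combined < 50) "high"
  else if (fcs_combined < 75) "medium"
  else "low_priority"
  out <- data.frame(species_id = species_id,
                    srs_ex = srs_ex, grs_ex = grs_ex, ers_ex = ers_ex,
                    fcs_ex = fcs_ex,
                    srs_in = srs_in, grs_in = grs_in, ers_in = ers_in,
                    fcs_in = fcs_in,
                    fcs_combined = fcs_combined, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_scores", class(out))
  out
}

#' Score one species end to end
#'
#' Computes all nine scores from scrubbed records, the species'
#' distribution raster (validated SDM presence if available, else CA50 on
#' all records), the ecoregion and protected-area layers.
#'
#' @param records scrubbed occurrence data frame for one species
#' @param distribution binary [raster_layer()]
#' @param ecoregions categorical [raster_layer()]
#' @param pa binary [raster_layer()]
#' @param mask binary land-mask [raster_layer()] (for the G buffer)
#' @param areas a [cell_area_model()] (defaults to the grid's)
#' @param ca50_km G-buffer radius in km
#' @return one-row `conservation_scores` data frame
#' @export
score_species <- function(records, distribution, ecoregions, pa, mask,
                          areas = cell_area_model(distribution$grid),
                          ca50_km = 50) {
  sid <- unique(as.character(records$species_id))
  if (length(sid) != 1L) stop("records must belong to one species")
  counts <- summarize_occurrences(records)
  g_geo <- records[records$record_type == "G" & !is.na(records$lon) &
                     !is.na(records$lat), , drop = FALSE]
  g_buffer <- if (nrow(g_geo) > 0L)
    ca50(g_geo, distribution$grid, mask, radius_km = ca50_km) else NULL
  ins <- insitu_scores(distribution, pa, ecoregions, records, areas)
  combine_and_categorize(sid,
                         srs_ex = srs_ex(counts),
                         grs_ex = grs_ex(g_buffer, distribution, areas),
                         ers_ex = ers_ex(g_buffer, distribution, ecoregions),
                         srs_in = ins[["srs_in"]], grs_in = ins[["grs_in"]],
                         ers_in = ins[["ers_in"]])
}
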