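#' Occurrence records
#'
#' Occurrence records are plain data frames with columns `species_id`,
#' `lon`, `lat` (decimal degrees, `NA` when not georeferenced), `iso3`,
#' `year` (integer or `NA`), `record_type` (`"G"` germplasm accession /
#' `"H"` reference record) and `native_status` (`"N"` native / `"I"`
#' introduced). The G/H distinction drives the ex situ sampling score:
#' G records are 'site where collected' locations of living accessions in
#' genebanks and similar repositories; H records (mostly herbarium and
#' observation records) inform distribution modeling only.
#'
#' @name occurrences
NULL

occurrence_columns <- c("species_id", "lon", "lat", "iso3", "year",
                        "record_type", "native_status")

#' Empty occurrence-record frame
#' @return zero-row data frame with the occurrence columns
#' @export
empty_occurrences <- function() {
  data.frame(species_id = character(0), lon = numeric(0), lat = numeric(0),
             iso3 = character(0), year = integer(0),
             record_type = character(0), native_status = character(0),
             stringsAsFactors = FALSE)
}

# GBIF basis-of-record categories that map to H (reference records)
GBIF_H_CATEGORIES <- c("observation", "literature", "preserved specimen",
                       "human observation", "machine observation",
                       "material sample", "unknown", "")

#' Classify a record as germplasm (G) or reference (H)
#'
#' GBIF records are classified from the basis-of-record field: "living
#' specimen" becomes G; observation, literature, preserved specimen, human
#' observation, machine observation, material sample, unknown and empty
#' become H. Unrecognized categories are treated as "unknown" (H) with a
#' warning. All Genesys records are G. Records from sources that arrive
#' pre-classified (`source = "cwr"`) pass their label through.
#'
#' @param basis_of_record character vector (may be empty strings); for
#'   `source = "cwr"` this carries the pre-assigned `"G"`/`"H"` label
#' @param source one of `"gbif"`, `"genesys"`, `"cwr"`
#' @return character vector of `"G"`/`"H"`
#' @export
classify_record_type <- function(basis_of_record,
                                 source = c("gbif", "genesys", "cwr")) {
  source <- match.arg(source)
  basis <- tolower(trimws(gsub("\\s+", " ", as.character(basis_of_record))))
  basis[is.na(basis)] <- ""
  switch(source,
         genesys = rep("G", length(basis)),
         cwr = toupper(basis),
         gbif = {
           out <- ifelse(basis == "living specimen", "G", "H")
           unknown <- !(basis %in% c("living specimen", GBIF_H_CATEGORIES))
           if (any(unknown)) {
             warning(sprintf("%d unrecognized basis-of-record value(s) treated as unknown (H): %s",
                             sum(unknown),
                             paste(unique(basis[unknown]), collapse = ", ")))
           }
           out
         })
}

#' Scrub occurrence records
#'
#' Removes records whose coordinates fall in water (land-mask test at cell
#' resolution), records outside the species' native range, and reference
#' records collected before `year_min` (records with no collecting date are
#' kept). Records without coordinates are retained — they still count for
#' the sampling score — but are excluded from modeling downstream.
#'
#' Each rejected record carries exactly one primary reason, assigned in the
#' fixed precedence order `off-grid > water > non-native > too-old` so
#' reports are deterministic for multi-violation records.
#'
#' The record's country is its `iso3` field when present; otherwise, if an
#' administrative polygon layer is supplied, the country containing the
#' point. A record whose country cannot be determined fails the native-range
#' test.
#'
#' @param records occurrence data frame (see [occurrences])
#' @param land_mask binary [raster_layer()] (1 = land)
#' @param native_countries character vector of ISO3 codes defining the
#'   species' native range
#' @param year_min minimum collecting year (default 1950)
#' @param admin_polygons optional list of [geo_polygon()] with an `iso3`
#'   attribute, used to assign a country to records lacking `iso3`
#' @return list with elements `kept` (data frame) and `rejected` (data
#'   frame with an extra `reason` column)
#' @export
scrub <- function(records, land_mask, native_countries, year_min = 1950,
                  admin_polygons = NULL) {
  stopifnot(inherits(land_mask, "raster_layer"),
            land_mask$semantics == "binary")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n > 0L) {
    has_coords <- !is.na(records$lon) & !is.na(records$lat)
    idx <- cell_index(land_mask$grid, records$lon, records$lat)
    off_grid <- has_coords & is.na(idx[, "row"])
    land <- layer_values(land_mask)
    in_water <- rep(FALSE, n)
    ok <- has_coords & !off_grid
    if (any(ok)) {
      cellv <- land[cbind(idx[ok, "row"], idx[ok, "col"])]
      in_water[ok] <- is.na(cellv) | cellv != 1
    }
    iso <- toupper(as.character(records$iso3))
    iso[is.na(iso) | iso == ""] <- NA_character_
    if (!is.null(admin_polygons)) {
      need <- which(is.na(iso) & has_coords)
      for (i in need) {
        for (p in admin_polygons) {
          if (point_in_polygon(records$lon[i], records$lat[i], p)) {
            iso[i] <- toupper(as.character(p$attrs$iso3)); break
          }
        }
      }
    }
    non_native <- is.na(iso) | !(iso %in% toupper(native_countries))
    too_old <- !is.na(records$year) & records$year < year_min

    reason[too_old] <- "too-old"
    reason[non_native] <- "non-native"
    reason[in_water] <- "water"
    reason[off_grid] <- "off-grid"
  }
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Per-species occurrence counts summary
#'
#' Produces the counts row consumed by the conservation-score step: total
#' and georeferenced record counts, split by G/H type. All records must
#' share one `species_id`.
#'
#' @param records occurrence data frame for a single species
#' @return one-row data frame with columns `species_id`, `total_records`,
#'   `total_with_coords`, `g_records`, `g_with_coords`, `h_records`,
#'   `h_with_coords`
#' @export
summarize_occurrences <- function(records) {
  sid <- unique(as.character(records$species_id))
  if (length(sid) > 1L) stop("records mix species_ids: ", paste(sid, collapse = ", "))
  if (length(sid) == 0L) sid <- NA_character_
  has_coords <- !is.na(records$lon) & !is.na(records$lat)
  is_g <- records$record_type == "G"
  data.frame(species_id = sid,
             total_records = nrow(records),
             total_with_coords = sum(has_coords),
             g_records = sum(is_g),
             g_with_coords = sum(is_g & has_coords),
             h_records = sum(!is_g),
             h_with_coords = sum(!is_g & has_coords),
             stringsAsFactors = FALSE)
}
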