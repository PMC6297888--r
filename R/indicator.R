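#' Indicator aggregation across geographic scopes
#'
#' Species-level conservation scores are combined into indicator values at
#' country, sub-regional, regional and global scales. A species contributes
#' to every scope whose member countries intersect its native range (full
#' membership, no fractional allocation); scope means are unweighted
#' arithmetic means of the species FCS values. Scopes follow the UN M49
#' statistical classification: countries nest in sub-regions, sub-regions
#' in regions, and the global scope holds every country.
#'
#' @name indicator
NULL

#' Scope definition
#'
#' @param scope_id ISO3 code, M49 code, or `"global"`
#' @param level one of `"country"`, `"sub_region"`, `"region"`, `"global"`
#' @param member_countries character vector of ISO3 codes
#' @param name human-readable scope name
#' @return list of class `scope_definition`
#' @export
scope_definition <- function(scope_id, level = c("country", "sub_region",
                                                 "region", "global"),
                             member_countries, name = scope_id) {
  level <- match.arg(level)
  member_countries <- toupper(member_countries)
  if (any(!grepl(ISO3_RE, member_countries))) {
    stop("malformed ISO3 code(s) in scope members")
  }
  structure(list(scope_id = as.character(scope_id), level = level,
                 member_countries = member_countries, name = name),
            class = "scope_definition")
}

#' Load M49-style classification tables into scopes
#'
#' Expects a table (data frame or CSV path) with columns `iso3`, `country`,
#' `sub_region_code`, `sub_region`, `region_code`, `region`. Produces one
#' scope per country, sub-region and region, plus the global scope. A
#' country listed under two different regions (or sub-regions) is an error:
#' sub-regions must partition their region's countries.
#'
#' @param classification data frame or CSV path
#' @return named list of [scope_definition()]
#' @export
load_m49 <- function(classification) {
  df <- if (is.character(classification) && length(classification) == 1L)
    utils::read.csv(classification, stringsAsFactors = FALSE)
  else as.data.frame(classification)
  df$iso3 <- toupper(df$iso3)
  dup <- df[duplicated(df$iso3) | duplicated(df$iso3, fromLast = TRUE), ]
  if (nrow(dup)) {
    if (anyDuplicated(unique(dup[, c("iso3", "sub_region_code",
                                     "region_code")])$iso3)) {
      stop("a country appears in more than one region or sub-region")
    }
    df <- df[!duplicated(df$iso3), ]
  }
  scopes <- list()
  for (i in seq_len(nrow(df))) {
    scopes[[df$iso3[i]]] <- scope_definition(df$iso3[i], "country",
                                             df$iso3[i], name = df$country[i])
  }
  for (sr in unique(df$sub_region_code)) {
    rows <- df[df$sub_region_code == sr, ]
    scopes[[as.character(sr)]] <- scope_definition(
      as.character(sr), "sub_region", rows$iso3, name = rows$sub_region[1L])
  }
  for (rg in unique(df$region_code)) {
    rows <- df[df$region_code == rg, ]
    scopes[[as.character(rg)]] <- scope_definition(
      as.character(rg), "region", rows$iso3, name = rows$region[1L])
  }
  scopes[["global"]] <- scope_definition("global", "global", df$iso3,
                                         name = "global")
  scopes
}

#' Species native to a scope
#'
#' A species belongs to a scope iff its native-country set intersects the
#' scope's member countries.
#'
#' @param entries named list of species entries (see [load_wep_tables()])
#' @param scope a [scope_definition()]
#' @return character vector of species ids
#' @export
species_for_scope <- function(entries, scope) {
  stopifnot(inherits(scope, "scope_definition"))
  keep <- vapply(entries, function(e)
    length(intersect(toupper(e$native_countries),
                     scope$member_countries)) > 0L, logical(1))
  names(entries)[keep]
}

#' Aggregate species scores over a scope
#'
#' Unweighted means of FCS ex situ, in situ and combined over the scope's
#' species, plus counts per priority category. Scope species missing a
#' score row are reported in `missing` and excluded from the means; an
#' empty scope yields `n_species = 0` and `NA` means.
#'
#' @param scores data frame of [combine_and_categorize()] rows (one per
#'   species)
#' @param scope_species character vector of species ids in the scope
#' @param scope_id identifier copied into the result
#' @param level scope level copied into the result
#' @return list of class `indicator_result`: `scope_id`, `level`,
#'   `n_species`, `mean_fcs_ex`, `mean_fcs_in`, `mean_fcs_combined`,
#'   `category_counts`, `missing`
#' @export
aggregate_scope <- function(scores, scope_species, scope_id = NA_character_,
                            level = NA_character_) {
  rows <- scores[scores$species_id %in% scope_species, , drop = FALSE]
  missing <- setdiff(scope_species, scores$species_id)
  if (length(missing)) {
    warning(sprintf("scope %s: %d species without scores excluded from means",
                    scope_id, length(missing)))
  }
  cats <- c("urgent", "high", "medium", "low_priority")
  counts <- stats::setNames(vapply(cats, function(ct)
    sum(rows$category == ct), 0L), cats)
  n <- nrow(rows)
  structure(list(scope_id = scope_id, level = level, n_species = n,
                 mean_fcs_ex = if (n) mean(rows$fcs_ex) else NA_real_,
                 mean_fcs_in = if (n) mean(rows$fcs_in) else NA_real_,
                 mean_fcs_combined = if (n) mean(rows$fcs_combined) else NA_real_,
                 category_counts = counts, missing = missing),
            class = "indicator_result")
}

#' Compute the indicator for every scope
#'
#' @param scores per-species scores data frame
#' @param entries named list of species entries (native ranges)
#' @param scopes named list of [scope_definition()] from [load_m49()]
#' @return data frame with one row per scope: scope id, level, name,
#'   species count, the three mean FCS values and the four category counts
#' @export
compute_indicator <- function(scores, entries, scopes) {
  rows <- lapply(scopes, function(sc) {
    res <- aggregate_scope(scores, species_for_scope(entries, sc),
                           scope_id = sc$scope_id, level = sc$level)
    data.frame(scope_id = res$scope_id, level = res$level, name = sc$name,
               n_species = res$n_species,
               mean_fcs_ex = res$mean_fcs_ex,
               mean_fcs_in = res$mean_fcs_in,
               mean_fcs_combined = res$mean_fcs_combined,
               n_urgent = res$category_counts[["urgent"]],
               n_high = res$category_counts[["high"]],
               n_medium = res$category_counts[["medium"]],
               n_low_priority = res$category_counts[["low_priority"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
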