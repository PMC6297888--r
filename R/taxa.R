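#' Species selection from WEP-style tables
#'
#' The indicator starts from three long-format tables in the layout of the
#' GRIN-Global World Economic Plants (WEP) extract: a names table (one row
#' per species), a uses table (one row per species x use category) and a
#' country-distribution table (one row per species x country, with a
#' native/introduced flag). Species enter the indicator when they have at
#' least one confirmed use outside the excluded categories and are not
#' strictly cultivated.
#'
#' @name taxa
NULL

ISO3_RE <- "^[A-Za-z]{3}$"

#' Selection configuration
#'
#' The excluded-use default encodes the selection rule: weeds, poisonous
#' plants, ornamentals, and plants listed only as potential (rather than
#' confirmed) genetic resources are dropped, as are strictly cultivated
#' species. Use-category codes are an opaque controlled vocabulary supplied
#' with the data.
#'
#' @param excluded_use_categories character vector of use codes that do not
#'   qualify a species
#' @param exclude_strictly_cultivated drop species flagged strictly
#'   cultivated in the names table
#' @return an object of class `selection_config`
#' @export
selection_config <- function(
    excluded_use_categories = c("weed", "poisonous", "ornamental",
                                "potential_genetic_resource_only"),
    exclude_strictly_cultivated = TRUE) {
  if (length(excluded_use_categories) == 0L) {
    stop("excluded_use_categories must be non-empty")
  }
  structure(list(excluded_use_categories = excluded_use_categories,
                 exclude_strictly_cultivated = isTRUE(exclude_strictly_cultivated)),
            class = "selection_config")
}

new_species_entry <- function(species_id, name, author = "",
                              strictly_cultivated = FALSE) {
  list(species_id = species_id, name = name, author = author,
       strictly_cultivated = strictly_cultivated,
       uses = character(0),
       native_countries = character(0), introduced_countries = character(0),
       standardized_name = NA_character_, name_standardized = FALSE)
}

#' Load and join WEP-style species tables
#'
#' @param names_table data frame (or CSV path) with columns `species_id`,
#'   `name`, optional `author` and logical `strictly_cultivated`
#' @param uses_table data frame (or CSV path) with columns `species_id`,
#'   `use`; one use per row, duplicates collapsed
#' @param distributions_table data frame (or CSV path) with columns
#'   `species_id`, `iso3`, `status` (`N` native / `I` introduced); one
#'   country per row
#' @return named list of species entries (one per distinct `species_id` in
#'   the names table, keyed and ordered by first appearance). Species ids
#'   appearing only in the uses/distributions tables are reported with a
#'   warning and dropped; rows with malformed ISO3 codes are rejected with
#'   a warning.
#' @export
load_wep_tables <- function(names_table, uses_table, distributions_table) {
  as_table <- function(x) if (is.character(x) && length(x) == 1L)
    utils::read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  names_table <- as_table(names_table)
  uses_table <- as_table(uses_table)
  distributions_table <- as_table(distributions_table)

  entries <- list()
  for (i in seq_len(nrow(names_table))) {
    sid <- as.character(names_table$species_id[i])
    if (!is.null(entries[[sid]])) next  # first row wins for duplicates
    entries[[sid]] <- new_species_entry(
      sid, as.character(names_table$name[i]),
      author = if ("author" %in% names(names_table))
        as.character(names_table$author[i]) else "",
      strictly_cultivated = if ("strictly_cultivated" %in% names(names_table))
        isTRUE(as.logical(names_table$strictly_cultivated[i])) else FALSE)
  }

  orphans <- character(0)
  for (i in seq_len(nrow(uses_table))) {
    sid <- as.character(uses_table$species_id[i])
    if (is.null(entries[[sid]])) { orphans <- c(orphans, sid); next }
    entries[[sid]]$uses <- union(entries[[sid]]$uses,
                                 as.character(uses_table$use[i]))
  }
  n_bad_iso <- 0L
  for (i in seq_len(nrow(distributions_table))) {
    sid <- as.character(distributions_table$species_id[i])
    iso <- toupper(as.character(distributions_table$iso3[i]))
    if (is.null(entries[[sid]])) { orphans <- c(orphans, sid); next }
    if (!grepl(ISO3_RE, iso)) { n_bad_iso <- n_bad_iso + 1L; next }
    status <- toupper(as.character(distributions_table$status[i]))
    if (status == "N") {
      entries[[sid]]$native_countries <-
        union(entries[[sid]]$native_countries, iso)
    } else {
      entries[[sid]]$introduced_countries <-
        union(entries[[sid]]$introduced_countries, iso)
    }
  }
  if (length(orphans)) {
    warning(sprintf("%d use/distribution rows reference species absent from the names table: %s",
                    length(orphans),
                    paste(unique(orphans), collapse = ", ")))
  }
  if (n_bad_iso) warning(sprintf("%d distribution rows rejected (malformed ISO3)", n_bad_iso))
  entries
}

#' Select the useful wild species that enter the indicator
#'
#' A species is retained iff it has at least one use outside the excluded
#' categories and (by default) is not strictly cultivated. The operation is
#' deterministic, order-preserving and idempotent.
#'
#' @param entries list of species entries from [load_wep_tables()]
#' @param config a [selection_config()]
#' @return the retained subset of `entries`
#' @export
select_useful_wild <- function(entries, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  keep <- vapply(entries, function(e) {
    qualifying <- setdiff(e$uses, config$excluded_use_categories)
    length(qualifying) >= 1L &&
      !(config$exclude_strictly_cultivated && isTRUE(e$strictly_cultivated))
  }, logical(1))
  entries[keep]
}

#' Apply an offline name-standardization mapping
#'
#' Names are standardized against a precomputed backbone mapping table
#' rather than a live taxonomic service. When two raw names map to the same
#' accepted name (synonyms), the entries are merged: uses and country sets
#' are unioned onto the first entry and the duplicate is dropped.
#'
#' @param entries list of species entries
#' @param mapping_table data frame with columns `raw_name`,
#'   `standardized_name`
#' @return updated entries; unmapped names keep their raw name with
#'   `name_standardized = FALSE`
#' @export
apply_name_standardization <- function(entries, mapping_table) {
  mapping_table <- as.data.frame(mapping_table)
  map <- stats::setNames(as.character(mapping_table$standardized_name),
                         as.character(mapping_table$raw_name))
  seen <- list()  # standardized name -> species_id of first carrier
  out <- list()
  n_merged <- 0L
  for (sid in names(entries)) {
    e <- entries[[sid]]
    std <- unname(map[e$name])
    if (!is.na(std)) {
      e$standardized_name <- std
      e$name_standardized <- TRUE
    } else {
      e$standardized_name <- e$name
      e$name_standardized <- FALSE
      std <- e$name
    }
    first <- seen[[std]]
    if (!is.null(first)) {
      f <- out[[first]]
      f$uses <- union(f$uses, e$uses)
      f$native_countries <- union(f$native_countries, e$native_countries)
      f$introduced_countries <- union(f$introduced_countries,
                                      e$introduced_countries)
      out[[first]] <- f
      n_merged <- n_merged + 1L
    } else {
      seen[[std]] <- sid
      out[[sid]] <- e
    }
  }
  if (n_merged) message(sprintf("%d synonym entr%s merged during name standardization",
                                n_merged, if (n_merged == 1L) "y" else "ies"))
  out
}
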