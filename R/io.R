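# Readers and writers for the delimited-text formats the pipeline consumes:
# Newick trees, taxon age tables, occurrence tables in the flavor of
# Paleobiology Database (PBDB) CSV exports, and per-bin covariate tables.

read_delim_auto <- function(path) {
  if (requireNamespace("readr", quietly = TRUE)) {
    as_tibble(readr::read_delim(path, show_col_types = FALSE, progress = FALSE))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE, check.names = FALSE))
  }
}

#' Read a Newick tree from a file
#'
#' @param path Path to a Newick file (first tree is returned).
#' @param ... Passed to [parse_newick()].
#' @return An [ape::phylo].
#' @export
read_newick <- function(path, ...) {
  text <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(text, ...)
}

#' Column mapping for PBDB-style occurrence exports
#'
#' Maps the canonical column names used throughout the package to the
#' column names of a raw PBDB CSV export. Override any entry to adapt other
#' flavors.
#'
#' @param taxon,latitude,longitude,state,time_bin,formation,collection_id
#'   Source column names.
#' @return A named character vector (canonical -> source).
#' @export
pbdb_column_map <- function(taxon = "accepted_name", latitude = "lat",
                            longitude = "lng", state = "state",
                            time_bin = "early_interval",
                            formation = "formation",
                            collection_id = "collection_no") {
  c(taxon = taxon, latitude = latitude, longitude = longitude, state = state,
    time_bin = time_bin, formation = formation, collection_id = collection_id)
}

#' Default state/province to region lookup for Laramidia
#'
#' Two-province rule: states/provinces from Wyoming northwards are
#' "north"; Utah and further south are "south". Editable: pass your own
#' named vector to [read_occurrences()].
#'
#' @return Named character vector mapping state/province to region.
#' @export
laramidia_regions <- function() {
  c(
    "Alaska" = "north", "Yukon" = "north", "Northwest Territories" = "north",
    "British Columbia" = "north", "Alberta" = "north",
    "Saskatchewan" = "north", "Manitoba" = "north",
    "Montana" = "north", "North Dakota" = "north", "South Dakota" = "north",
    "Idaho" = "north", "Wyoming" = "north",
    "Utah" = "south", "Colorado" = "south", "Nevada" = "south",
    "Arizona" = "south", "New Mexico" = "south", "Texas" = "south",
    "Sonora" = "south", "Chihuahua" = "south", "Coahuila" = "south",
    "Baja California" = "south"
  )
}

#' Read an occurrence table, mapping PBDB-style columns
#'
#' Reads a delimited occurrence export, renames columns via `column_map`,
#' and derives the `region` column from the state/province through
#' `region_lookup` (records from unmapped states get `NA` region and a
#' warning). If the source already has a `region` column it is kept as is.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named vector from [pbdb_column_map()].
#' @param region_lookup Named vector mapping state/province to region;
#'   default [laramidia_regions()].
#' @return A tibble with canonical columns `taxon`, `region`, `latitude`,
#'   `longitude`, `time_bin`, `formation`, `collection_id`.
#' @export
read_occurrences <- function(path, column_map = pbdb_column_map(),
                             region_lookup = laramidia_regions()) {
  raw <- read_delim_auto(path)
  out <- tibble(.rows = nrow(raw))
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  if ("region" %in% names(raw)) {
    out$region <- raw$region
  } else {
    out$region <- unname(region_lookup[as.character(out$state)])
    if (anyNA(out$region)) {
      warn(paste0(
        "No region mapping for state(s): ",
        paste(unique(out$state[is.na(out$region)]), collapse = ", ")
      ))
    }
  }
  if (is.na(column_map[["taxon"]]) || !"taxon" %in% names(out)) {
    abort("Occurrence table lacks a taxon column.")
  }
  out[, c("taxon", "region", "latitude", "longitude", "time_bin",
          "formation", "collection_id", "state")]
}

#' Read a taxon age table
#'
#' Expects columns `taxon`, `fad_ma`, `lad_ma` and optionally `time_bins`
#' (semicolon-separated bin names). Missing `time_bins` are derived from
#' the default Campanian/Maastrichtian boundaries.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble.
#' @export
read_taxon_ages <- function(path) {
  df <- read_delim_auto(path)
  need <- c("taxon", "fad_ma", "lad_ma")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("Age table lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (any(df$fad_ma < df$lad_ma, na.rm = TRUE)) {
    abort("FAD must be >= LAD for every taxon.")
  }
  if (!"time_bins" %in% names(df)) {
    df$time_bins <- purrr::map2_chr(df$fad_ma, df$lad_ma, bins_for_range)
  }
  df
}

#' Read a per-bin covariate table
#'
#' One row per 1-degree latitudinal bin; must contain `bin_floor`.
#'
#' @param path Path to a CSV/TSV file.
#' @return A tibble sorted by `bin_floor`.
#' @export
read_covariates <- function(path) {
  df <- read_delim_auto(path)
  if (!"bin_floor" %in% names(df)) abort("Covariate table lacks `bin_floor`.")
  dplyr::arrange(df, .data$bin_floor)
}

#' Serialize a result object to JSON
#'
#' Writes resampling or connectedness results as a JSON record including
#' the seed and configuration needed to reproduce them.
#'
#' @param x A package result object (`pbc_resample`, `pbc_permutation`,
#'   `pbc_subsample`, a pBC tibble, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  payload <- if (inherits(x, "pbc_resample")) {
    list(type = "resample", label = x$label, n_reps = x$n_reps,
         seed = x$seed, observed = x$observed, summary = x$summary,
         values = x$values)
  } else if (inherits(x, "pbc_permutation")) {
    list(type = "permutation", observed = x$observed, p_value = x$p_value,
         alternative = x$alternative, n_reps = x$n_reps, seed = x$seed,
         mu = x$mu, null_values = x$null_values)
  } else if (inherits(x, "pbc_subsample")) {
    list(type = "subsample", removal_fraction = x$removal_fraction,
         lat_band = x$lat_band, n_band_taxa = x$n_band_taxa,
         prob_leq = as.list(x$prob_leq), seed = x$seed,
         summary = x$distribution$summary, values = x$distribution$values)
  } else {
    x
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
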