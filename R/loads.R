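#' Pollen-load records
#'
#' A load collection is a flat table with one row per (load, constituent):
#' loads have variable numbers of constituents, so the delimited layout keeps
#' a `load_id` to group rows. Each load records the bee species it came from,
#' the farm and survey round, its size in eighths of a full scopal load
#' (1--8), and the percentage of the load's volume contributed by each pollen
#' taxon. Constituent percentages of a load must sum to 100 (+/- 0.5, to
#' absorb rounded field estimates).
#'
#' @param df data.frame with columns `load_id`, `bee_species`, `farm_id`,
#'   `round_id`, `load_size_eighths`, `plant_taxon`, `proportion_pct`.
#' @param taxonomy optional `pollen_taxonomy`; when given, every
#'   `plant_taxon` must resolve against it.
#' @return A validated `pollen_loads` data.frame (row order preserved).
#' @export
pollen_loads <- function(df, taxonomy = NULL) {
  required <- c("load_id", "bee_species", "farm_id", "round_id",
                "load_size_eighths", "plant_taxon", "proportion_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("loads table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$load_id <- as.character(df$load_id)
  df$bee_species <- trimws(as.character(df$bee_species))
  df$plant_taxon <- trimws(as.character(df$plant_taxon))
  df$load_size_eighths <- as.integer(df$load_size_eighths)
  df$proportion_pct <- as.numeric(df$proportion_pct)

  bad_size <- is.na(df$load_size_eighths) |
    df$load_size_eighths < 1L | df$load_size_eighths > 8L
  if (any(bad_size)) {
    stop("load size outside 1..8 eighths: row(s) ",
         paste(which(bad_size), collapse = ", "))
  }
  bad_prop <- is.na(df$proportion_pct) |
    df$proportion_pct <= 0 | df$proportion_pct > 100
  if (any(bad_prop)) {
    stop("constituent proportion outside (0, 100]: row(s) ",
         paste(which(bad_prop), collapse = ", "))
  }

  if (!is.null(taxonomy)) {
    idx <- taxon_index(taxonomy, df$plant_taxon)
    if (anyNA(idx)) {
      stop("unknown taxon label(s) in loads: row(s) ",
           paste(which(is.na(idx)), collapse = ", "), " (",
           paste(unique(df$plant_taxon[is.na(idx)]), collapse = ", "), ")")
    }
  }

  by_load <- split(seq_len(nrow(df)), df$load_id)
  for (rows in by_load) {
    total <- sum(df$proportion_pct[rows])
    if (abs(total - 100) > 0.5) {
      stop("constituent proportions of load '", df$load_id[rows[1]],
           "' sum to ", format(total), ", not 100 (+/- 0.5): row(s) ",
           paste(rows, collapse = ", "))
    }
    if (anyDuplicated(taxon_key(df$plant_taxon[rows]))) {
      stop("duplicate constituent taxa in load '", df$load_id[rows[1]],
           "': row(s) ", paste(rows, collapse = ", "))
    }
    if (length(unique(df$load_size_eighths[rows])) != 1 ||
        length(unique(df$bee_species[rows])) != 1) {
      stop("inconsistent size or bee species within load '",
           df$load_id[rows[1]], "'")
    }
  }
  class(df) <- c("pollen_loads", "data.frame")
  df
}

#' Read and write pollen-load collections
#'
#' CSV header: `load_id,bee_species,farm_id,round_id,load_size_eighths,`
#' `plant_taxon,proportion_pct`. `write_loads()` followed by `read_loads()`
#' is the identity on any valid collection.
#'
#' @param path path to a CSV file.
#' @param taxonomy optional `pollen_taxonomy` used to validate taxon labels.
#' @return `read_loads()` returns a `pollen_loads` data.frame;
#'   `write_loads()` returns `path` invisibly.
#' @export
read_loads <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("loads file not found: ", path)
  pollen_loads(utils::read.csv(path, stringsAsFactors = FALSE), taxonomy)
}

#' @rdname read_loads
#' @param loads a `pollen_loads` data.frame.
#' @export
write_loads <- function(loads, path) {
  utils::write.csv(as.data.frame(loads), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Survey occurrence records
#'
#' One row per (bee species, farm) pair with the number of sightings over
#' the survey period. CSV header: `bee_species,farm_id,n_sightings`.
#'
#' @param df data.frame with the three columns above.
#' @return A validated `occurrence_table` data.frame.
#' @export
occurrence_table <- function(df) {
  required <- c("bee_species", "farm_id", "n_sightings")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("occurrence table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$bee_species <- trimws(as.character(df$bee_species))
  df$n_sightings <- as.integer(df$n_sightings)
  if (any(is.na(df$n_sightings) | df$n_sightings < 0)) {
    stop("n_sightings must be non-negative integers")
  }
  key <- paste(taxon_key(df$bee_species), df$farm_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (bee_species, farm_id) pair(s) in occurrence table")
  }
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' @rdname occurrence_table
#' @param path path to a CSV file.
#' @export
read_occurrence <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  occurrence_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Frequency of occurrence of a bee species across farms
#'
#' Counts the farms where the species was recorded at least once. A species
#' absent from the table has frequency 0.
#'
#' @param occ an `occurrence_table`.
#' @param bee_species single bee species name.
#' @return Non-negative integer count of farms.
#' @examples
#' occ <- occurrence_table(data.frame(
#'   bee_species = "Andrena flavipes", farm_id = c("A", "B"),
#'   n_sightings = c(3L, 0L)
#' ))
#' farm_occurrence(occ, "Andrena flavipes")  # 1
#' @export
farm_occurrence <- function(occ, bee_species) {
  stopifnot(length(bee_species) == 1)
  hit <- taxon_key(occ$bee_species) == taxon_key(bee_species) &
    occ$n_sightings >= 1
  length(unique(occ$farm_id[hit]))
}
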