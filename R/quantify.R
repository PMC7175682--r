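#' Exclude minor load constituents
#'
#' Constituents contributing less than `threshold` percent of a load's volume
#' are treated as probable contamination and removed; the remaining
#' proportions are rescaled so each load stays compositional (sums to 100).
#' A constituent at exactly the threshold is kept.
#'
#' @param loads a `pollen_loads` data.frame.
#' @param threshold percent cut-off below which constituents are dropped.
#' @return A `pollen_loads` data.frame with minor constituents removed and
#'   per-load proportions renormalised to 100.
#' @examples
#' # a 99.5/0.5 load becomes a pure load
#' @export
filter_minor_constituents <- function(loads, threshold = 1.0) {
  df <- as.data.frame(loads)
  keep <- rep(TRUE, nrow(df))
  by_load <- split(seq_len(nrow(df)), df$load_id)
  for (rows in by_load) {
    minor <- df$proportion_pct[rows] < threshold
    if (all(minor)) {
      stop("all constituents of load '", df$load_id[rows[1]],
           "' fall below the ", threshold, "% threshold")
    }
    keep[rows[minor]] <- FALSE
    kept <- rows[!minor]
    df$proportion_pct[kept] <-
      100 * df$proportion_pct[kept] / sum(df$proportion_pct[kept])
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pollen_loads", "data.frame")
  out
}

#' Weight load constituents by load size
#'
#' Converts raw per-load percentages into final weights in percent-load
#' units: weight = (load size in eighths / 8) x proportion, so a full load
#' totals 100 and a quarter (2/8) load composed entirely of one species
#' contributes 25. Weighting by estimated volume rather than by load count
#' makes the aggregate reflect the total volume of pollen collected.
#'
#' @param loads a `pollen_loads` data.frame (minor constituents already
#'   excluded).
#' @return The same table with an added `weight` column.
#' @examples
#' tax <- pollen_taxonomy(data.frame(
#'   taxon_label = c("Centaurea nigra", "Leucanthemum vulgare"),
#'   genus = c("Centaurea", "Leucanthemum"),
#'   family = c("Asteraceae", "Asteraceae"),
#'   resolution = "species"
#' ))
#' full_5050 <- pollen_loads(data.frame(
#'   load_id = "L1", bee_species = "Bee", farm_id = "F", round_id = "R",
#'   load_size_eighths = 8L,
#'   plant_taxon = c("Centaurea nigra", "Leucanthemum vulgare"),
#'   proportion_pct = c(50, 50)
#' ), tax)
#' weight_load(full_5050)$weight  # 50 50
#' @export
weight_load <- function(loads) {
  df <- as.data.frame(loads)
  df$weight <- (df$load_size_eighths / 8) * df$proportion_pct
  class(df) <- c("pollen_loads", "data.frame")
  df
}

#' Construct a diet profile
#'
#' Low-level constructor for the per-bee-species aggregate: volume-weighted
#' percentage composition at pollen-taxon, genus and family level, plus the
#' percentage of loads that are pure (single-group) loads of each group and
#' the percentage of loads containing each group. Fixture-derived profiles
#' may omit levels the source table does not print (`species_level`,
#' `genus_level` may be `NULL`; pure/presence maps may carry only the
#' preferred host).
#'
#' @param bee_species bee species name.
#' @param n_loads number of loads aggregated (>= 1).
#' @param family_level named numeric vector of family percentages (sums to
#'   100 +/- 0.5).
#' @param species_level,genus_level optional named percentage vectors.
#' @param pure_load_pct,presence_pct lists with elements `taxon`, `genus`,
#'   `family`, each a named percentage vector (possibly partial).
#' @return A `diet_profile` object.
#' @export
diet_profile <- function(bee_species, n_loads, family_level,
                         species_level = NULL, genus_level = NULL,
                         pure_load_pct = list(), presence_pct = list()) {
  stopifnot(length(bee_species) == 1, n_loads >= 1)
  check_comp <- function(x, what) {
    if (is.null(x)) return(invisible())
    if (is.null(names(x)) || any(names(x) == "")) {
      stop(what, " shares must be named")
    }
    if (abs(sum(x) - 100) > 0.5) {
      stop(what, " shares sum to ", format(sum(x)), ", not 100 (+/- 0.5)")
    }
  }
  check_comp(family_level, "family-level")
  check_comp(species_level, "species-level")
  check_comp(genus_level, "genus-level")
  for (lev in names(pure_load_pct)) {
    pure <- pure_load_pct[[lev]]
    pres <- presence_pct[[lev]]
    common <- intersect(names(pure), names(pres))
    if (any(pure[common] > pres[common] + 1e-8)) {
      stop("pure-load percentage exceeds presence percentage at ",
           lev, " level")
    }
  }
  structure(
    list(bee_species = bee_species, n_loads = as.integer(n_loads),
         species_level = species_level, genus_level = genus_level,
         family_level = family_level,
         pure_load_pct = pure_load_pct, presence_pct = presence_pct),
    class = "diet_profile"
  )
}

#' @export
print.diet_profile <- function(x, ...) {
  cat("Diet profile:", x$bee_species, "(", x$n_loads, "loads )\n")
  fam <- sort(x$family_level, decreasing = TRUE)
  cat(paste0(names(fam), " ", formatC(fam, format = "f", digits = 1),
             collapse = ", "), "\n")
  invisible(x)
}

group_stats <- function(df, groups, total_weight) {
  # share of total weight, pure-load % and presence % per group
  share <- 100 * tapply(df$weight, groups, sum) / total_weight
  share <- share[order(-share)]
  loads <- split(groups, df$load_id)
  n_loads <- length(loads)
  all_groups <- names(share)
  pure <- presence <- numeric(length(all_groups))
  names(pure) <- names(presence) <- all_groups
  for (g in loads) {
    u <- unique(g)
    presence[u] <- presence[u] + 1
    if (length(u) == 1) pure[u] <- pure[u] + 1
  }
  list(share = c(share), pure = 100 * pure / n_loads,
       presence = 100 * presence / n_loads)
}

#' Aggregate one bee species' loads into a diet profile
#'
#' Pools the volume-corrected weights of all loads of one bee species:
#' the share of each pollen taxon is its summed weight as a percentage of
#' the species' total summed weight, and likewise at genus and family level
#' after mapping taxa through the taxonomy. Also records, per taxon / genus /
#' family, the percentage of loads that are pure loads of that group and the
#' percentage of loads containing it. Apply
#' [filter_minor_constituents()] first; the pure-load test then counts loads
#' whose filtered composition is a single group.
#'
#' @param loads a `pollen_loads` data.frame, all rows from one bee species.
#' @param taxonomy a `pollen_taxonomy` resolving every `plant_taxon`.
#' @return A `diet_profile`.
#' @export
aggregate_profile <- function(loads, taxonomy) {
  df <- as.data.frame(loads)
  if (nrow(df) == 0) stop("cannot aggregate an empty load collection")
  if (length(unique(df$bee_species)) != 1) {
    stop("loads from more than one bee species: ",
         paste(unique(df$bee_species), collapse = ", "))
  }
  if (is.null(df$weight)) df <- weight_load(df)
  total <- sum(df$weight)
  n_loads <- length(unique(df$load_id))

  idx <- taxon_index(taxonomy, df$plant_taxon)
  if (anyNA(idx)) {
    stop("unknown taxon label(s): ",
         paste(unique(df$plant_taxon[is.na(idx)]), collapse = ", "))
  }
  taxa <- taxonomy$taxon_label[idx]          # canonical spelling
  genera <- taxon_genus(taxonomy, df$plant_taxon)
  families <- taxon_family(taxonomy, df$plant_taxon)

  st <- group_stats(df, taxa, total)
  gt <- group_stats(df, genera, total)
  ft <- group_stats(df, families, total)

  diet_profile(
    bee_species = df$bee_species[1], n_loads = n_loads,
    species_level = st$share, genus_level = gt$share,
    family_level = ft$share,
    pure_load_pct = list(taxon = st$pure, genus = gt$pure, family = ft$pure),
    presence_pct = list(taxon = st$presence, genus = gt$presence,
                        family = ft$presence)
  )
}

#' Aggregate profiles for every bee species in a load collection
#'
#' @param loads a `pollen_loads` data.frame (any number of bee species).
#' @param taxonomy a `pollen_taxonomy`.
#' @return Named list of `diet_profile` objects, one per bee species.
#' @export
aggregate_profiles <- function(loads, taxonomy) {
  df <- as.data.frame(loads)
  out <- lapply(split(df, df$bee_species), function(d) {
    class(d) <- c("pollen_loads", "data.frame")
    aggregate_profile(d, taxonomy)
  })
  out[order(names(out))]
}

#' Count the plant families in a diet
#'
#' Number of families contributing at least `minor_threshold` percent of the
#' species' total weighted pollen. A pooled residual entry (e.g. `other` in
#' published tables) counts as one family when it reaches the threshold,
#' since it contains at least one.
#'
#' @param profile a `diet_profile`.
#' @param minor_threshold percent share below which a family is ignored.
#' @return Positive integer.
#' @export
count_families <- function(profile, minor_threshold = 1.0) {
  sum(profile$family_level >= minor_threshold)
}

#' Flatten diet profiles to a long table
#'
#' One row per (bee species, level, taxon) with the weighted share and the
#' pure-load / presence percentages, suitable for CSV export. Header:
#' `bee_species,level,taxon,share_pct,pure_pct,presence_pct,n_loads`.
#'
#' @param profiles list of `diet_profile` objects.
#' @return data.frame.
#' @export
profiles_table <- function(profiles) {
  if (inherits(profiles, "diet_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    per_level <- lapply(c(taxon = "species_level", genus = "genus_level",
                          family = "family_level"), function(f) p[[f]])
    names(per_level) <- c("taxon", "genus", "family")
    do.call(rbind, lapply(names(per_level), function(lev) {
      share <- per_level[[lev]]
      if (is.null(share)) return(NULL)
      pure <- p$pure_load_pct[[lev]]
      pres <- p$presence_pct[[lev]]
      data.frame(bee_species = p$bee_species, level = lev,
                 taxon = names(share), share_pct = unname(share),
                 pure_pct = unname(pure[names(share)]),
                 presence_pct = unname(pres[names(share)]),
                 n_loads = p$n_loads, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
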