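fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "pollendiet")
  if (path == "") {
    # source tree fallback (package not installed)
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("fixture not found: ", file)
  path
}

#' Reference diet profiles of 31 farmland solitary bee species
#'
#' Published family-level diet compositions, pure-load and presence
#' percentages, sample sizes and host-range categories for the 31 solitary
#' bee species of a three-year survey of 19 English farms (the species with
#' at least three analysed pollen loads). The source table prints family
#' composition (with a pooled `other` residual), so the reconstructed
#' `diet_profile`s carry `family_level` shares plus, for the two narrowly
#' oligolectic species (whose single host plant pins down the genus), a
#' genus-level share; pure-load and presence percentages refer to the
#' preferred host. See `inst/extdata/README.md` for transcription notes.
#'
#' @return List with elements `profiles` (named list of `diet_profile`) and
#'   `meta` (data.frame: `bee_species`, `bee_family`, `n_loads`,
#'   `n_localities`, `pure_pct`, `presence_pct`, `preferred_host`,
#'   `printed_category`).
#' @export
farmland_profiles <- function() {
  shares <- utils::read.csv(fixture_path("farmland_family_shares.csv"),
                            stringsAsFactors = FALSE)
  meta <- utils::read.csv(fixture_path("farmland_species_meta.csv"),
                          stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(nrow(meta)), function(i) {
    sp <- meta$bee_species[i]
    rows <- shares[shares$bee_species == sp, , drop = FALSE]
    fam <- rows[rows$level == "family", , drop = FALSE]
    gen <- rows[rows$level == "genus", , drop = FALSE]
    family_level <- stats::setNames(fam$share_pct, fam$taxon)
    genus_level <- if (nrow(gen) > 0) {
      stats::setNames(gen$share_pct, gen$taxon)
    } else NULL
    top_family <- names(family_level)[which.max(family_level)]
    pure <- list(family = stats::setNames(meta$pure_pct[i], top_family))
    pres <- list(family = stats::setNames(meta$presence_pct[i], top_family))
    if (!is.null(genus_level)) {
      # single-host-species diets: the preferred genus' pure/presence equal
      # the family's
      pure$genus <- stats::setNames(meta$pure_pct[i], names(genus_level))
      pres$genus <- stats::setNames(meta$presence_pct[i], names(genus_level))
    }
    diet_profile(bee_species = sp, n_loads = meta$n_loads[i],
                 family_level = family_level, genus_level = genus_level,
                 pure_load_pct = pure, presence_pct = pres)
  })
  names(profiles) <- meta$bee_species
  list(profiles = profiles, meta = meta)
}

#' Reference diet-breadth table (observation vs pollen loads)
#'
#' Published per-species counts of plant species and plant families detected
#' by direct observation and by pollen-load analysis, plus the published
#' rarefied richness at 12 loads for the species with at least 10 loads.
#' The two narrowly oligolectic species are excluded (29 rows).
#'
#' @return data.frame with columns `bee_species`, `n_observations`,
#'   `n_loads`, `obs_plant_species`, `pollen_plant_species`, `rarefied_12`,
#'   `obs_families`, `pollen_families`.
#' @export
farmland_breadth <- function() {
  utils::read.csv(fixture_path("farmland_diet_breadth.csv"),
                  stringsAsFactors = FALSE)
}
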