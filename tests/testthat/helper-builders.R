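# shared builders for small in-code fixtures

demo_taxonomy <- function() {
  pollen_taxonomy(data.frame(
    taxon_label = c("Centaurea nigra", "Leucanthemum vulgare",
                    "Hypochaeris radicata", "Brassica",
                    "Heracleum sphondylium", "Daucus carota",
                    "Bryonia dioica", "Trifolium repens"),
    genus = c("Centaurea", "Leucanthemum", "Hypochaeris", "Brassica",
              "Heracleum", "Daucus", "Bryonia", "Trifolium"),
    family = c("Asteraceae", "Asteraceae", "Asteraceae", "Brassicaceae",
               "Apiaceae", "Apiaceae", "Cucurbitaceae", "Fabaceae"),
    resolution = c("species", "species", "species", "genus",
                   "species", "species", "species", "species"),
    stringsAsFactors = FALSE
  ))
}

# one load as (load, constituent) rows; comp is a named percentage vector
load_rows <- function(id, comp, size = 8L, bee = "Bee test",
                      farm = "Farm_A", round = "R1") {
  data.frame(load_id = id, bee_species = bee, farm_id = farm,
             round_id = round, load_size_eighths = as.integer(size),
             plant_taxon = names(comp), proportion_pct = unname(comp),
             stringsAsFactors = FALSE)
}

demo_loads <- function(..., taxonomy = demo_taxonomy()) {
  pollen_loads(do.call(rbind, list(...)), taxonomy)
}

# profile with family-level information only (shape of published tables)
family_profile <- function(bee, family_level, pure, presence = NULL,
                           n_loads = 10L, genus_level = NULL,
                           genus_pure = NULL) {
  top <- names(family_level)[which.max(family_level)]
  if (is.null(presence)) presence <- pmin(100, pure)
  pp <- list(family = stats::setNames(pure, top))
  pr <- list(family = stats::setNames(presence, top))
  if (!is.null(genus_level)) {
    pp$genus <- stats::setNames(genus_pure, names(genus_level))
    pr$genus <- stats::setNames(genus_pure, names(genus_level))
  }
  diet_profile(bee_species = bee, n_loads = n_loads,
               family_level = family_level, genus_level = genus_level,
               pure_load_pct = pp, presence_pct = pr)
}
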