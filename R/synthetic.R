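#' Synthetic foraging scenario
#'
#' Parameterises a generative stand-in for a field pollen-load survey, with
#' known ground truth. Each bee species gets a true diet: a probability
#' vector over the plant community, drawn from a symmetric Dirichlet for
#' polylects or concentrated on one family / genus for oligolect ground
#' truth. Loads mix flower constancy with multi-host foraging: with
#' probability `constancy` a load is a pure load of a single host drawn from
#' the true diet; otherwise its composition is a normalised multinomial
#' sample of size `mixed_load_k` from the true diet. Load sizes are discrete
#' eighths (1--8). Frequency of occurrence is generated as a binomial over
#' `n_farms` with success probability increasing in true diet breadth, so
#' the breadth--occurrence association the statistics must recover is built
#' in without asserting any particular published effect size.
#'
#' @param n_plant_species plant community size (default 60).
#' @param n_families number of plant families, assigned round-robin
#'   (default 20; within a family, species are grouped into genera of two).
#' @param n_farms number of farms surveyed (default 19).
#' @param n_bees number of bee species (default 31).
#' @param n_loads_per_bee loads collected per bee species (default 10).
#' @param templates per-bee diet template, `"polylectic"`,
#'   `"oligolectic_family"` or `"oligolectic_genus"`; recycled or truncated
#'   to `n_bees`. The default mirrors the composition of the reference
#'   survey's characterised community: 26 polylects, 3 family oligolects,
#'   2 genus oligolects.
#' @param constancy probability in (0, 1] that a load is a single-host pure
#'   load (default 0.5).
#' @param dirichlet_alpha symmetric Dirichlet concentration for polylectic
#'   true diets (default 0.3: a few dominant hosts plus a tail).
#' @param mixed_load_k multinomial sample size composing a mixed load
#'   (default 6).
#' @param load_size_probs probabilities of load sizes 1..8 eighths (default
#'   uniform).
#' @param occurrence_intercept,occurrence_slope logit-scale intercept and
#'   per-plant-species slope of the farm-occupancy probability. The defaults
#'   spread expected occupancy from a handful of farms for single-host
#'   specialists to most of the 19 farms for the broadest polylects,
#'   matching the range the reference survey observed.
#' @param breadth_floor minimum true probability for a plant species to
#'   count towards true diet breadth (default 0.01).
#' @param seed integer seed (default 1).
#' @return A `foraging_scenario` list of the validated parameters.
#' @export
foraging_scenario <- function(n_plant_species = 60, n_families = 20,
                              n_farms = 19, n_bees = 31,
                              n_loads_per_bee = 10,
                              templates = c(rep("polylectic", 26),
                                            rep("oligolectic_family", 3),
                                            rep("oligolectic_genus", 2)),
                              constancy = 0.5, dirichlet_alpha = 0.3,
                              mixed_load_k = 6,
                              load_size_probs = rep(1 / 8, 8),
                              occurrence_intercept = -2,
                              occurrence_slope = 0.2,
                              breadth_floor = 0.01, seed = 1L) {
  if (n_families > n_plant_species) {
    stop("more families (", n_families, ") than plant species (",
         n_plant_species, ")")
  }
  stopifnot(constancy >= 0, constancy <= 1, dirichlet_alpha > 0,
            mixed_load_k >= 1, length(load_size_probs) == 8,
            all(load_size_probs >= 0), sum(load_size_probs) > 0,
            n_farms >= 1, n_bees >= 1, n_loads_per_bee >= 0)
  templates <- rep_len(templates, n_bees)
  bad <- !templates %in% c("polylectic", "oligolectic_family",
                           "oligolectic_genus")
  if (any(bad)) stop("unknown template(s): ",
                     paste(unique(templates[bad]), collapse = ", "))
  structure(list(
    n_plant_species = as.integer(n_plant_species),
    n_families = as.integer(n_families), n_farms = as.integer(n_farms),
    n_bees = as.integer(n_bees),
    n_loads_per_bee = as.integer(n_loads_per_bee), templates = templates,
    constancy = constancy, dirichlet_alpha = dirichlet_alpha,
    mixed_load_k = as.integer(mixed_load_k),
    load_size_probs = load_size_probs / sum(load_size_probs),
    occurrence_intercept = occurrence_intercept,
    occurrence_slope = occurrence_slope, breadth_floor = breadth_floor,
    seed = as.integer(seed)), class = "foraging_scenario")
}

scenario_taxonomy <- function(scenario) {
  S <- scenario$n_plant_species
  fam_idx <- ((seq_len(S) - 1) %% scenario$n_families) + 1
  # within a family, group successive species into genera of two
  pos <- stats::ave(seq_len(S), fam_idx, FUN = seq_along)
  pollen_taxonomy(data.frame(
    taxon_label = sprintf("Species_%03d", seq_len(S)),
    genus = sprintf("Genus_%02d_%d", fam_idx, ceiling(pos / 2)),
    family = sprintf("Family_%02d", fam_idx),
    resolution = "species", stringsAsFactors = FALSE
  ))
}

scenario_diet <- function(scenario, taxonomy, template, bee_index) {
  S <- scenario$n_plant_species
  p <- numeric(S)
  if (template == "polylectic") {
    g <- stats::rgamma(S, shape = scenario$dirichlet_alpha)
    if (sum(g) == 0) g[sample.int(S, 1)] <- 1
    p <- g / sum(g)
  } else {
    groups <- if (template == "oligolectic_family") taxonomy$family else
      taxonomy$genus
    pool <- unique(groups)
    host <- pool[((bee_index - 1) %% length(pool)) + 1]
    members <- which(groups == host)
    g <- stats::rgamma(length(members), shape = 1)
    if (sum(g) == 0) g <- rep(1, length(members))
    p[members] <- g / sum(g)
  }
  p
}

round_composition <- function(shares) {
  # round to 0.1% and push the residual into the largest constituent so the
  # composition still sums to exactly 100
  r <- round(shares * 10) / 10
  r[which.max(r)] <- r[which.max(r)] + (100 - sum(r))
  r
}

#' Generate the pollen loads of one bee
#'
#' Draws `n_loads` loads from a bee's true diet under the scenario's
#' constancy mixture: a pure single-host load with probability `constancy`,
#' otherwise a normalised multinomial mixture of `mixed_load_k` draws, with
#' proportions rounded to 0.1%. Load sizes are sampled from the scenario's
#' size distribution; farms and survey rounds are sampled uniformly from
#' those supplied.
#'
#' @param diet probability vector over the scenario's plant species.
#' @param scenario a `foraging_scenario`.
#' @param taxonomy the scenario taxonomy (see [generate_scenario()]).
#' @param bee_species label for the generated loads.
#' @param farms character vector of farms the bee occurs on.
#' @param n_loads number of loads to draw (defaults to the scenario's).
#' @param id_prefix prefix for load identifiers.
#' @return A `pollen_loads` data.frame (zero rows if `n_loads` is 0).
#' @export
generate_loads <- function(diet, scenario, taxonomy, bee_species = "Bee_01",
                           farms = "Farm_01",
                           n_loads = scenario$n_loads_per_bee,
                           id_prefix = bee_species) {
  stopifnot(length(diet) == scenario$n_plant_species,
            abs(sum(diet) - 1) < 1e-8)
  rows <- vector("list", n_loads)
  if (n_loads == 0) {
    empty <- data.frame(load_id = character(0), bee_species = character(0),
                        farm_id = character(0), round_id = character(0),
                        load_size_eighths = integer(0),
                        plant_taxon = character(0),
                        proportion_pct = numeric(0))
    class(empty) <- c("pollen_loads", "data.frame")
    return(empty)
  }
  for (j in seq_len(n_loads)) {
    size <- sample.int(8, 1, prob = scenario$load_size_probs)
    if (stats::runif(1) <= scenario$constancy) {
      taxa <- sample.int(length(diet), 1, prob = diet)
      props <- 100
    } else {
      counts <- stats::rmultinom(1, scenario$mixed_load_k, diet)[, 1]
      taxa <- which(counts > 0)
      props <- round_composition(100 * counts[taxa] / sum(counts[taxa]))
    }
    rows[[j]] <- data.frame(
      load_id = sprintf("%s_L%04d", id_prefix, j),
      bee_species = bee_species,
      farm_id = if (length(farms) == 1) farms else sample(farms, 1),
      round_id = sprintf("R%d", sample.int(4, 1)),
      load_size_eighths = size,
      plant_taxon = taxonomy$taxon_label[taxa],
      proportion_pct = props, stringsAsFactors = FALSE)
  }
  pollen_loads(do.call(rbind, rows), taxonomy)
}

#' Exact diet profile implied by a true diet
#'
#' Converts a bee's true diet probabilities into the `diet_profile` the
#' pipeline would estimate from infinitely many loads: exact shares at all
#' three levels, and the theoretical pure-load / presence percentages under
#' the scenario's constancy mixture (a load is pure for group g with
#' probability c p_g + (1 - c) p_g^k, and contains g with probability
#' c p_g + (1 - c) (1 - (1 - p_g)^k)).
#'
#' @param diet probability vector over plant species.
#' @param scenario a `foraging_scenario`.
#' @param taxonomy the scenario taxonomy.
#' @param bee_species label.
#' @return A `diet_profile`.
#' @export
true_profile <- function(diet, scenario, taxonomy, bee_species = "Bee_01") {
  keep <- diet > 0
  groups <- list(
    taxon = taxonomy$taxon_label,
    genus = taxonomy$genus,
    family = taxonomy$family
  )
  cc <- scenario$constancy
  k <- scenario$mixed_load_k
  shares <- pure <- pres <- list()
  for (lev in names(groups)) {
    p_g <- tapply(diet, groups[[lev]], sum)
    p_g <- p_g[p_g > 0]
    p_g <- c(p_g[order(-p_g)])
    shares[[lev]] <- 100 * p_g
    pure[[lev]] <- 100 * (cc * p_g + (1 - cc) * p_g^k)
    pres[[lev]] <- 100 * (cc * p_g + (1 - cc) * (1 - (1 - p_g)^k))
  }
  diet_profile(bee_species = bee_species, n_loads = .Machine$integer.max,
               species_level = shares$taxon, genus_level = shares$genus,
               family_level = shares$family,
               pure_load_pct = pure, presence_pct = pres)
}

#' Realise a synthetic survey
#'
#' Draws the whole synthetic data set a field survey would produce, plus the
#' ground truth: the plant taxonomy, each bee species' true diet and true
#' host-range category (the decision tree applied to the exact true
#' profile), the load-level records, and a farm-occurrence table in which
#' each bee occupies `max(1, Binomial(n_farms, plogis(a + b * breadth)))`
#' farms. Reproducible: the same scenario (including its seed) yields
#' byte-identical outputs.
#'
#' @param scenario a `foraging_scenario`.
#' @param cfg `lecty_config` used for the ground-truth categories.
#' @param out_dir optional directory; when given, `taxonomy.csv`,
#'   `loads.csv`, `occurrence.csv` and `truth.csv` are written there.
#' @return List: `scenario`, `taxonomy` (`pollen_taxonomy`), `loads`
#'   (`pollen_loads`), `occurrence` (`occurrence_table`), `truth`
#'   (data.frame: `bee_species`, `bee_family`, `template`, `true_category`,
#'   `true_breadth`, `true_n_farms`), `diets` (bees x species probability
#'   matrix).
#' @export
generate_scenario <- function(scenario, cfg = lecty_config(),
                              out_dir = NULL) {
  stopifnot(inherits(scenario, "foraging_scenario"))
  taxonomy <- scenario_taxonomy(scenario)
  out <- local_seed(scenario$seed, {
    n_bees <- scenario$n_bees
    bee_species <- sprintf("Bee_species_%02d", seq_len(n_bees))
    bee_family <- c("Andrenidae", "Halictidae")[(seq_len(n_bees) - 1) %% 2 + 1]
    farm_ids <- sprintf("Farm_%02d", seq_len(scenario$n_farms))

    diets <- matrix(0, n_bees, scenario$n_plant_species,
                    dimnames = list(bee_species, taxonomy$taxon_label))
    truth <- vector("list", n_bees)
    occ <- vector("list", n_bees)
    loads <- vector("list", n_bees)
    for (i in seq_len(n_bees)) {
      diet <- scenario_diet(scenario, taxonomy, scenario$templates[i], i)
      diets[i, ] <- diet
      breadth <- sum(diet >= scenario$breadth_floor)
      p_occ <- stats::plogis(scenario$occurrence_intercept +
                               scenario$occurrence_slope * breadth)
      n_occ <- max(1L, stats::rbinom(1, scenario$n_farms, p_occ))
      farms <- sort(sample(farm_ids, n_occ))
      occ[[i]] <- data.frame(bee_species = bee_species[i], farm_id = farms,
                             n_sightings = 1L + stats::rpois(n_occ, 2),
                             stringsAsFactors = FALSE)
      loads[[i]] <- generate_loads(diet, scenario, taxonomy,
                                   bee_species = bee_species[i],
                                   farms = farms)
      tp <- true_profile(diet, scenario, taxonomy, bee_species[i])
      truth[[i]] <- data.frame(
        bee_species = bee_species[i], bee_family = bee_family[i],
        template = scenario$templates[i],
        true_category = classify(tp, cfg)$category,
        true_breadth = breadth, true_n_farms = n_occ,
        stringsAsFactors = FALSE)
    }
    loads <- do.call(rbind, loads)
    class(loads) <- c("pollen_loads", "data.frame")
    list(scenario = scenario, taxonomy = taxonomy, loads = loads,
         occurrence = occurrence_table(do.call(rbind, occ)),
         truth = do.call(rbind, truth), diets = diets)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(out$taxonomy),
                     file.path(out_dir, "taxonomy.csv"), row.names = FALSE)
    write_loads(out$loads, file.path(out_dir, "loads.csv"))
    utils::write.csv(as.data.frame(out$occurrence),
                     file.path(out_dir, "occurrence.csv"), row.names = FALSE)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  out
}

#' Parameter-recovery experiment over replicated synthetic surveys
#'
#' Runs the full pipeline (minor-constituent filter, weighting, aggregation,
#' classification, rarefaction, breadth--occurrence fit) over replicated
#' realisations of a scenario at each sample size in `n_loads_grid`, against
#' the known ground truth. Reports, per sample size: the category-recovery
#' rate (estimated category equals true category, by template); the mean
#' bias of exact rarefied breadth at `target_loads` relative to the
#' rarefied true diet; and the proportion of replicates whose fitted
#' breadth--occurrence slope is positive / significant at 0.05 (replicates
#' with at least 3 bees). Rarefied breadth uses the closed-form
#' [rarefy_exact()] (identical in expectation to the Monte-Carlo procedure).
#'
#' @param scenario a `foraging_scenario` (its `n_loads_per_bee` is
#'   overridden by the grid, its seed by `seed` + replicate).
#' @param n_loads_grid sample sizes to simulate at.
#' @param n_replicates replicates per sample size.
#' @param target_loads rarefaction target in loads (default 3).
#' @param cfg `lecty_config`.
#' @param seed base seed.
#' @return List of data.frames: `category_recovery` (template, n_loads,
#'   recovery_rate, n_bees), `breadth_bias` (n_loads, mean_bias, sd_bias),
#'   `occurrence_fit` (n_loads, prop_positive_slope, prop_significant,
#'   n_replicates).
#' @export
recovery_experiment <- function(scenario, n_loads_grid = c(3, 10, 20),
                                n_replicates = 50, target_loads = 3,
                                cfg = lecty_config(), seed = 1L) {
  cat_rows <- bias_rows <- fit_rows <- list()
  for (g in n_loads_grid) {
    hits <- list()
    biases <- c()
    slope_pos <- slope_sig <- logical(0)
    for (r in seq_len(n_replicates)) {
      sc <- scenario
      sc$n_loads_per_bee <- as.integer(g)
      sc$seed <- as.integer(seed + 7919L * match(g, n_loads_grid) + r)
      sim <- generate_scenario(sc, cfg)
      profiles <- aggregate_profiles(
        filter_minor_constituents(sim$loads), sim$taxonomy)
      est <- vapply(profiles, function(p) classify(p, cfg)$category,
                    character(1))
      truth <- sim$truth
      hits[[r]] <- data.frame(
        template = truth$template,
        hit = est[truth$bee_species] == truth$true_category)

      breadth <- rep(NA_real_, nrow(truth))
      names(breadth) <- truth$bee_species
      for (i in seq_len(nrow(truth))) {
        b <- truth$bee_species[i]
        counts <- integer_transform(profiles[[b]]$species_level, g, b)
        true_counts <- integer_transform(
          100 * sim$diets[b, sim$diets[b, ] > 0], g, b)
        n_sub <- min(target_loads * 10, counts$total_units,
                     true_counts$total_units)
        breadth[i] <- rarefy_exact(counts, min(n_sub, counts$total_units))
        biases <- c(biases, breadth[i] -
                      rarefy_exact(true_counts,
                                   min(n_sub, true_counts$total_units)))
      }
      if (nrow(truth) >= 3 && length(unique(breadth)) > 1) {
        fit <- gaussian_linear_fit(
          data.frame(n_farms = truth$true_n_farms,
                     rarefied_breadth = unname(breadth)))
        slope <- fit$coefficients[
          fit$coefficients$term == "rarefied_breadth", ]
        slope_pos <- c(slope_pos, slope$estimate > 0)
        slope_sig <- c(slope_sig, slope$p < 0.05)
      }
    }
    hits <- do.call(rbind, hits)
    agg <- stats::aggregate(hit ~ template, data = hits,
                            FUN = function(x) c(rate = mean(x), n = length(x)))
    cat_rows[[length(cat_rows) + 1]] <- data.frame(
      template = agg$template, n_loads = g,
      recovery_rate = agg$hit[, "rate"], n_bees = agg$hit[, "n"])
    bias_rows[[length(bias_rows) + 1]] <- data.frame(
      n_loads = g, mean_bias = mean(biases), sd_bias = stats::sd(biases))
    if (length(slope_pos) > 0) {
      fit_rows[[length(fit_rows) + 1]] <- data.frame(
        n_loads = g, prop_positive_slope = mean(slope_pos),
        prop_significant = mean(slope_sig), n_replicates = length(slope_pos))
    }
  }
  list(category_recovery = do.call(rbind, cat_rows),
       breadth_bias = do.call(rbind, bias_rows),
       occurrence_fit = if (length(fit_rows) > 0) do.call(rbind, fit_rows)
                        else NULL)
}
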