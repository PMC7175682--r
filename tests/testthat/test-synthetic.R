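test_that("a scenario is reproducible and writes schema-valid files", {
  sc <- foraging_scenario(n_bees = 4, n_loads_per_bee = 6, seed = 5)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sim1 <- generate_scenario(sc, out_dir = dir1)
  sim2 <- generate_scenario(sc, out_dir = dir2)
  for (f in c("taxonomy.csv", "loads.csv", "occurrence.csv", "truth.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # generated files validate against the record schemas with zero errors
  tax <- read_taxonomy(file.path(dir1, "taxonomy.csv"))
  loads <- read_loads(file.path(dir1, "loads.csv"), tax)
  occ <- read_occurrence(file.path(dir1, "occurrence.csv"))
  expect_equal(length(unique(loads$load_id)), 4 * 6)
  expect_true(all(unique(loads$bee_species) %in% occ$bee_species))
})

test_that("full constancy yields single-constituent loads only", {
  sc <- foraging_scenario(n_bees = 3, n_loads_per_bee = 8, constancy = 1,
                          seed = 9)
  sim <- generate_scenario(sc)
  per_load <- table(sim$loads$load_id)
  expect_true(all(per_load == 1))
  expect_true(all(sim$loads$proportion_pct == 100))
})

test_that("single-family ground truth produces family-pure loads", {
  sc <- foraging_scenario(n_bees = 2, templates = "oligolectic_family",
                          constancy = 0.4, n_loads_per_bee = 10, seed = 13)
  sim <- generate_scenario(sc)
  fam <- taxon_family(sim$taxonomy, sim$loads$plant_taxon)
  for (b in unique(sim$loads$bee_species)) {
    expect_equal(length(unique(fam[sim$loads$bee_species == b])), 1L)
  }
  # a single-species community forces every load to be that species
  sc1 <- foraging_scenario(n_plant_species = 1, n_families = 1, n_bees = 1,
                           n_loads_per_bee = 5, constancy = 0.5, seed = 3)
  sim1 <- generate_scenario(sc1)
  expect_true(all(sim1$loads$plant_taxon == "Species_001"))
  expect_true(all(sim1$loads$proportion_pct == 100))

  # zero loads is an empty, well-formed collection
  sc0 <- foraging_scenario(n_bees = 1, n_loads_per_bee = 0, seed = 2)
  expect_equal(nrow(generate_scenario(sc0)$loads), 0L)
})

test_that("mixed-load compositions average to the true diet", {
  # two equally likely hosts, never flower-constant, pairs per load:
  # long-run mean share per host approaches 50%
  sc <- foraging_scenario(n_plant_species = 2, n_families = 1, n_bees = 1,
                          n_loads_per_bee = 2000, constancy = 1e-9,
                          mixed_load_k = 2, dirichlet_alpha = 1, seed = 17)
  tax <- generate_scenario(sc)$taxonomy
  set.seed(17)
  loads <- generate_loads(c(0.5, 0.5), sc, tax, n_loads = 2000)
  p <- aggregate_profile(loads, tax)
  expect_lt(max(abs(p$species_level - 50)), 2)
})

test_that("aggregated shares converge to the true diet as loads grow", {
  sc <- foraging_scenario(n_plant_species = 8, n_families = 3, n_bees = 1,
                          n_loads_per_bee = 3000, constancy = 0.5,
                          dirichlet_alpha = 2, seed = 23)
  sim <- generate_scenario(sc)
  p <- aggregate_profile(sim$loads, sim$taxonomy)
  truth <- 100 * sim$diets[1, ]
  est <- p$species_level[names(truth)]
  est[is.na(est)] <- 0
  expect_lt(max(abs(unname(est) - unname(truth))), 3)
})

test_that("ground-truth categories equal the decision tree on the exact profile", {
  sc <- foraging_scenario(
    n_bees = 6, n_loads_per_bee = 5,
    templates = c("polylectic", "oligolectic_family", "oligolectic_genus"),
    seed = 29)
  sim <- generate_scenario(sc)
  for (i in seq_len(sc$n_bees)) {
    tp <- true_profile(sim$diets[i, ], sc, sim$taxonomy,
                       sim$truth$bee_species[i])
    expect_equal(classify(tp)$category, sim$truth$true_category[i])
  }
  # oligolect templates imply oligolectic ground truth
  olig <- sim$truth$template != "polylectic"
  expect_true(all(sim$truth$true_category[olig] %in%
                    c("broadly_oligolectic", "narrowly_oligolectic")))
})

test_that("scenario configuration is validated", {
  expect_error(foraging_scenario(n_plant_species = 3, n_families = 5),
               "more families")
  expect_error(foraging_scenario(templates = "nectar_robber"),
               "unknown template")
})

test_that("misclassification is worse at 3 loads than at 20", {
  sc <- foraging_scenario(n_bees = 5, constancy = 0.5, seed = 37)
  rec <- recovery_experiment(sc, n_loads_grid = c(3, 20), n_replicates = 25,
                             seed = 37)
  cr <- rec$category_recovery
  expect_lt(cr$recovery_rate[cr$n_loads == 3],
            cr$recovery_rate[cr$n_loads == 20])
  # rarefied-breadth bias is reported and small at the larger sample size
  expect_true(all(is.finite(rec$breadth_bias$mean_bias)))
  expect_true(all(rec$occurrence_fit$prop_positive_slope >= 0))
})
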