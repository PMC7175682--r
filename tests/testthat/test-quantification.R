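test_that("minor constituents are excluded and loads renormalised", {
  loads <- demo_loads(
    load_rows("L1", c("Centaurea nigra" = 99.5, "Brassica" = 0.5)),
    load_rows("L2", c("Centaurea nigra" = 50, "Brassica" = 50)),
    load_rows("L3", c("Centaurea nigra" = 97, "Brassica" = 2,
                      "Bryonia dioica" = 1))
  )
  out <- filter_minor_constituents(loads)
  l1 <- out[out$load_id == "L1", ]
  expect_equal(l1$plant_taxon, "Centaurea nigra")
  expect_equal(l1$proportion_pct, 100)
  expect_equal(out[out$load_id == "L2", ]$proportion_pct, c(50, 50))
  # a constituent at exactly the threshold is kept
  expect_equal(nrow(out[out$load_id == "L3", ]), 3L)
  expect_equal(out[out$load_id == "L3", ]$proportion_pct, c(97, 2, 1))

  expect_error(
    filter_minor_constituents(
      demo_loads(load_rows("L1", c("Centaurea nigra" = 50, "Brassica" = 50))),
      threshold = 60),
    "all constituents")
})

test_that("load weights scale proportions by load size in eighths", {
  # full 50/50 load keeps weights 50/50; quarter pure load weighs 25
  loads <- demo_loads(
    load_rows("L1", c("Centaurea nigra" = 50, "Leucanthemum vulgare" = 50),
              size = 8L),
    load_rows("L2", c("Hypochaeris radicata" = 100), size = 2L),
    load_rows("L3", c("Centaurea nigra" = 30, "Brassica" = 70), size = 4L)
  )
  w <- weight_load(loads)
  expect_equal(w$weight[w$load_id == "L1"], c(50, 50))
  expect_equal(w$weight[w$load_id == "L2"], 25)
  expect_equal(w$weight[w$load_id == "L3"], c(15, 35))
})

test_that("weight conservation: a load's weights total 100 x size / 8", {
  set.seed(11)
  tax <- demo_taxonomy()
  for (i in 1:20) {
    k <- sample(1:4, 1)
    props <- as.vector(stats::rmultinom(1, 200, rep(1 / k, k))) / 2
    props <- props[props > 0]
    size <- sample(1:8, 1)
    comp <- stats::setNames(props, sample(tax$taxon_label, length(props)))
    w <- weight_load(demo_loads(load_rows(paste0("L", i), comp, size = size)))
    expect_equal(sum(w$weight), 100 * size / 8, tolerance = 1e-8)
  }
})

test_that("profiles aggregate weighted shares, pure loads and presence", {
  tax <- demo_taxonomy()
  two_fam <- demo_loads(
    load_rows("L1", c("Centaurea nigra" = 100)),
    load_rows("L2", c("Heracleum sphondylium" = 100))
  )
  p <- aggregate_profile(two_fam, tax)
  expect_equal(p$family_level[c("Asteraceae", "Apiaceae")],
               c(Asteraceae = 50, Apiaceae = 50))
  expect_equal(p$pure_load_pct$family[["Asteraceae"]], 50)
  expect_equal(p$presence_pct$family[["Asteraceae"]], 50)

  # repeated pure loads of one species give a 100/100/100 row
  pure3 <- demo_loads(
    load_rows("P1", c("Bryonia dioica" = 100)),
    load_rows("P2", c("Bryonia dioica" = 100)),
    load_rows("P3", c("Bryonia dioica" = 100))
  )
  q <- aggregate_profile(pure3, tax)
  expect_equal(q$family_level, c(Cucurbitaceae = 100))
  expect_equal(unname(q$pure_load_pct$family), 100)
  expect_equal(unname(q$presence_pct$family), 100)

  # volume weighting: a full load outweighs a quarter load 100 : 25
  sized <- demo_loads(
    load_rows("S1", c("Centaurea nigra" = 100), size = 8L),
    load_rows("S2", c("Brassica" = 100), size = 2L)
  )
  s <- aggregate_profile(sized, tax)
  expect_equal(s$species_level,
               c("Centaurea nigra" = 80, "Brassica" = 20))

  expect_error(aggregate_profile(two_fam[0, ], tax), "empty")
  mixed <- as.data.frame(two_fam)
  mixed$bee_species[1] <- "Other bee"
  expect_error(aggregate_profile(mixed, tax), "more than one bee species")
})

test_that("family shares are the push-forward of species shares", {
  set.seed(21)
  sc <- foraging_scenario(n_bees = 3, n_plant_species = 12, n_families = 4,
                          n_loads_per_bee = 15, seed = 21)
  sim <- generate_scenario(sc)
  profiles <- aggregate_profiles(sim$loads, sim$taxonomy)
  for (p in profiles) {
    fam_of <- taxon_family(sim$taxonomy, names(p$species_level))
    pushed <- tapply(p$species_level, fam_of, sum)
    expect_equal(sort(c(pushed)), sort(p$family_level), tolerance = 1e-8)
    # pure loads are a subset of loads containing the taxon
    for (lev in c("taxon", "genus", "family")) {
      expect_true(all(p$pure_load_pct[[lev]] <=
                        p$presence_pct[[lev]] + 1e-8))
    }
  }
})

test_that("duplicating every load leaves all profile percentages unchanged", {
  tax <- demo_taxonomy()
  base <- demo_loads(
    load_rows("L1", c("Centaurea nigra" = 70, "Brassica" = 30), size = 6L),
    load_rows("L2", c("Hypochaeris radicata" = 100), size = 3L)
  )
  doubled <- as.data.frame(base)
  copy <- doubled
  copy$load_id <- paste0(copy$load_id, "_dup")
  doubled <- pollen_loads(rbind(doubled, copy), tax)
  p1 <- aggregate_profile(base, tax)
  p2 <- aggregate_profile(doubled, tax)
  expect_equal(p1$species_level, p2$species_level)
  expect_equal(p1$family_level, p2$family_level)
  expect_equal(p1$pure_load_pct, p2$pure_load_pct)
  expect_equal(p1$presence_pct, p2$presence_pct)
  expect_equal(p2$n_loads, 2L * p1$n_loads)
})

test_that("family counting applies the minor-share threshold inclusively", {
  expect_equal(count_families(family_profile(
    "b", c(AST = 67.8, BRA = 32.0, other = 0.2), pure = 42.9)), 2L)
  expect_equal(count_families(family_profile(
    "b", c(FAB = 100), pure = 100)), 1L)
  expect_equal(count_families(family_profile(
    "b", c(F1 = 50, F2 = 49, F3 = 1.0), pure = 10)), 3L)
})
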