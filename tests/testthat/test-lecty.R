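test_that("volume criterion passes at 95% of pollen from one group", {
  cfg <- lecty_config()
  expect_true(criterion_volume(family_profile(
    "b", c(API = 97, other = 3), pure = 33.3), "family", cfg)$passes)
  expect_true(criterion_volume(family_profile(
    "b", c(F = 100), pure = 100), "family", cfg)$passes)
  v <- criterion_volume(family_profile(
    "b", c(F = 94.9, G = 5.1), pure = 50), "family", cfg)
  expect_false(v$passes)
  expect_equal(v$value, 94.9)
})

test_that("pure-load criterion passes at 90% pure loads of one group", {
  cfg <- lecty_config()
  expect_false(criterion_pure_loads(family_profile(
    "b", c(AST = 95.3, RAN = 4.7), pure = 71.4), "family", cfg)$passes)
  expect_true(criterion_pure_loads(family_profile(
    "b", c(CUC = 100), pure = 100), "family", cfg)$passes)
  expect_false(criterion_pure_loads(family_profile(
    "b", c(F = 100), pure = 89.9), "family", cfg)$passes)
})

test_that("the decision tree reproduces reference species of every category", {
  fx <- farmland_profiles()$profiles
  expect_equal(classify(fx[["Lasioglossum leucozonium"]])$category,
               "polylectic_strong_preference")
  florea <- classify(fx[["Andrena florea"]])
  expect_equal(florea$category, "narrowly_oligolectic")
  expect_equal(florea$preferred_host, "Bryonia")
  expect_equal(classify(fx[["Andrena minutuloides"]])$category,
               "broadly_oligolectic")
  expect_equal(classify(fx[["Lasioglossum xanthopus"]])$category,
               "mesolectic")
  expect_equal(classify(fx[["Andrena scotica"]])$category, "polylectic_ss")
})

test_that("species below the minimum sample size are refused", {
  small <- family_profile("b", c(F = 100), pure = 100, n_loads = 2L)
  err <- tryCatch(classify(small), condition = function(c) c)
  expect_s3_class(err, "insufficient_sample")
  expect_match(conditionMessage(err), "insufficient sample")
  # the same profile classifies once the minimum is relaxed
  expect_equal(classify(small, lecty_config(min_loads = 2))$category,
               "broadly_oligolectic")
})

test_that("classification is deterministic and monotone in the top share", {
  p <- family_profile("b", c(AST = 80, BRA = 20), pure = 50, presence = 90)
  expect_identical(classify(p), classify(p))

  # raising the top family's share never lowers the specialisation rank
  # (profiles with three families throughout: a two-family diet crossing the
  # strong-preference cut legitimately moves mesolectic -> strong preference,
  # which the category lattice ranks lower)
  ranks <- sapply(seq(34, 97, by = 3), function(s) {
    classify(family_profile(
      "b", c(AST = s, BRA = (100 - s) * 0.6, ROS = (100 - s) * 0.4),
      pure = 50, presence = 90))$rank
  })
  expect_true(all(diff(ranks) >= 0))
})

test_that("when the two criteria disagree the less specialised branch wins", {
  # volume passes, pure loads fail: falls through to strong preference
  p <- family_profile("b", c(API = 97, other = 3), pure = 33.3,
                      presence = 100)
  r <- classify(p)
  expect_true(r$verdicts$volume_family$passes)
  expect_false(r$verdicts$pure_family$passes)
  expect_equal(r$category, "polylectic_strong_preference")

  # pure loads pass, volume fails: same outcome
  q <- family_profile("b", c(API = 94, BRA = 6), pure = 92, presence = 100)
  expect_equal(classify(q)$category, "polylectic_strong_preference")
})

test_that("reference-table concordance is stable across the admissible strong-preference band", {
  fx <- farmland_profiles()
  ref <- stats::setNames(fx$meta$printed_category, fx$meta$bee_species)
  # the reference table brackets the threshold between 68.1 (polylectic
  # s.s.) and 73.1 (strong preference); any cut inside the band gives the
  # same concordance
  for (thr in c(68.2, 70, 72, 73.1)) {
    cfg <- lecty_config(strong_pref_threshold = thr)
    res <- classify_table(fx$profiles, cfg, reference = ref)
    expect_equal(unname(attr(res, "concordance")["matches"]), 30,
                 label = paste("threshold", thr))
  }
})

test_that("single-family diets with full constancy are recovered as oligolectic at 10 loads", {
  sc <- foraging_scenario(n_bees = 1, templates = "oligolectic_family",
                          constancy = 1, n_loads_per_bee = 10)
  hits <- vapply(1:25, function(s) {
    sc$seed <- 1000L + s
    sim <- generate_scenario(sc)
    profiles <- aggregate_profiles(filter_minor_constituents(sim$loads),
                                   sim$taxonomy)
    classify(profiles[[1]])$category %in%
      c("broadly_oligolectic", "narrowly_oligolectic")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("classify_table handles empty input and reports exclusions", {
  empty <- classify_table(list())
  expect_equal(nrow(empty), 0L)
  res <- classify_table(list(
    family_profile("tiny", c(F = 100), pure = 100, n_loads = 2L),
    family_profile("ok", c(F = 100), pure = 100, n_loads = 5L)))
  expect_equal(attr(res, "excluded"), "tiny")
  expect_equal(res$bee_species, "ok")
})
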