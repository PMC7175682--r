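# pollendiet

Pollen-load diet analysis for wild bees: quantify scopal pollen loads into
volume-weighted diet profiles, classify each bee species' host range
(lecty), standardise diet breadth by rarefaction, and relate diet breadth
to frequency of occurrence across farms. Written for pollination ecologists
working with microscopic pollen-load data (or survey data of the same
shape), and shipped with a synthetic foraging-data generator that provides
ground truth for validating the whole chain.

## The analysis

A raw record is one female bee's scopal load: its size in eighths of a full
load and the percentage of its volume from each pollen taxon. The pipeline:

1. **Filter & weight.** Constituents < 1% of a load are removed as probable
   contamination (proportions renormalised); each remaining percentage is
   weighted by load size, weight = (size/8) × proportion, so a full load
   totals 100 percent-load units and a quarter load 25.
2. **Aggregate.** Per bee species, the share of each taxon / genus / family
   is its summed weight over the species total, plus the percentage of
   loads that are *pure* loads of each group and the percentage containing
   it.
3. **Classify host range** under the dual criteria: oligolectic if ≥ 95% of
   pollen volume comes from one genus/family *and* ≥ 90% of loads are pure
   loads of it; when the criteria disagree, the less specialised category
   wins. Non-oligolects fall to polylectic-with-a-strong-preference (top
   family ≥ 70%), mesolectic (≤ 2 families), or polylectic s.s.
4. **Rarefy diet breadth.** Shares are integer-transformed (share × loads ×
   10, rounded), then target × 10 units are drawn without replacement 1000
   times; expected richness E[S] = Σ_t (1 − C(N−N_t, n)/C(N, n)) is also
   available in closed form (`rarefy_exact`).
5. **Relate breadth to occurrence.** Gaussian linear model of farms
   occupied on rarefied breadth (optional bee-family / farm-type factors)
   for well-sampled species; Spearman's rank correlation otherwise;
   Mann–Whitney rank-sum tests for observation-vs-pollen breadth
   comparisons.

A published 31-species reference table of farmland solitary bee diets is
packaged (`farmland_profiles()`, `farmland_breadth()`; see
`inst/extdata/README.md`), and the host-range decision tree reproduces 30
of its 31 printed categories — the single discordance is a species whose
printed oligolecty contradicts the stated combination rule, a discrepancy
the source study itself flags as doubtful.

## Worked example

```r
library(pollendiet)

tax <- pollen_taxonomy(data.frame(
  taxon_label = c("Centaurea nigra", "Leucanthemum vulgare"),
  genus = c("Centaurea", "Leucanthemum"),
  family = "Asteraceae", resolution = "species"))

load <- pollen_loads(data.frame(
  load_id = "L1", bee_species = "Demo bee", farm_id = "F1", round_id = "R1",
  load_size_eighths = 8L,
  plant_taxon = c("Centaurea nigra", "Leucanthemum vulgare"),
  proportion_pct = c(50, 50)), tax)

weight_load(load)[, c("plant_taxon", "proportion_pct", "weight")]
#>            plant_taxon proportion_pct weight
#> 1      Centaurea nigra             50     50
#> 2 Leucanthemum vulgare             50     50
```

A full 50/50 load yields weights 50/50 (a 2/8 load at 100% would yield 25).
Classifying the packaged reference profiles and re-computing the
observation-vs-pollen comparison:

```r
fx <- farmland_profiles()
cls <- classify_table(fx$profiles, lecty_config(),
                      reference = setNames(fx$meta$printed_category,
                                           fx$meta$bee_species))
attr(cls, "concordance")
#> matches   total
#>      30      31

breadth <- farmland_breadth()
rank_sum_test(breadth$obs_plant_species, breadth$pollen_plant_species)$statistic
#> [1] 211.5
```

Direct observation recorded a mean of 6.9 plant species per bee species
against 13.6 detected in pollen loads (W = 211.5, p = 0.001): pollen-load
analysis sees roughly twice the diet that transect observation does.

## Analysis workflow

Numbered scripts under `analysis/` run the study end to end on synthetic
data and on the packaged reference tables, writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R              # synthetic 31-species survey
Rscript analysis/02_characterise.R          # pipeline + ground-truth check
Rscript analysis/03_reference_reanalysis.R  # reference-table reanalysis
Rscript analysis/04_recovery.R              # parameter-recovery experiment
```

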