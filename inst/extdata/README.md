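# Reference fixtures

Hand-transcribed summary tables from a published three-year pollen-load survey
of solitary bees on 19 lowland English farms (Hampshire / West Sussex). The
tables describe the 31 bee species for which at least three scopal pollen
loads were analysed by light microscopy. Only these aggregated, published
summaries are shipped; the raw load-level records were never made public, so
the per-species rarefied values and the breadth-vs-occurrence regression of
the original study cannot be recomputed from what is here.

## farmland_family_shares.csv

One row per (bee species, pollen taxon): the percentage of that species'
total volume-weighted pollen (all loads pooled, <1% constituents excluded
per load) contributed by each plant family. Family codes: ACE Aceraceae,
API Apiaceae, AST Asteraceae, BER Berberidaceae, BRA Brassicaceae,
CAM Campanulaceae, CAP Caprifoliaceae, CAR Caryophyllaceae,
CUC Cucurbitaceae, FAB Fabaceae, GER Geraniaceae, LAM Lamiaceae,
LIL Liliaceae, MAL Malvaceae, OLE Oleaceae, ORO Orobanchaceae,
RAN Ranunculaceae, RES Resedaceae, RHA Rhamnaceae, ROS Rosaceae,
RUB Rubiaceae, SOL Solanaceae, VER Veronicaceae. `other` pools the
remaining families of the row. Two `genus`-level rows carry the host-genus
share for the two narrowly oligolectic species (their single host plant is a
single species, so the genus share equals the family share).

Transcription notes: three rows of the typeset table do not sum to 100 as
printed (Andrena bicolor 98.7, Andrena haemorrhoa 98.2, Halictus tumulorum
~102.0, the latter with anomalous three-digit decimals). For those rows the
named-family shares are kept as printed and the pooled `other` share is
recomputed as 100 minus their sum, so every stored row is compositional
(sums to 100 +/- 0.5). All other rows are verbatim.

## farmland_species_meta.csv

Per-species metadata: bee family; `n_loads` analysed; `n_localities`, the
number of farms the loads came from (published as metadata only — no
computation uses it); `pure_pct`, the percentage of the species' loads that
were pure (single-taxon after the <1% filter) loads of the preferred host;
`presence_pct`, the percentage of loads containing the preferred host at
all; the preferred host; and the host-range category printed in the source
table, recoded to this package's category labels (`narrowly_oligolectic`,
`broadly_oligolectic`, `mesolectic`, `polylectic_strong_preference`,
`polylectic_ss`).

## farmland_diet_breadth.csv

Per-species diet breadth by the two detection methods, excluding the two
narrowly oligolectic species (29 rows): number of pollen-foraging
observations (`n_observations`) and analysed loads (`n_loads`); counts of
distinct plant species and plant families recorded by direct observation
vs detected in pollen loads; and the published rarefied richness at a
standardised 12 loads (`rarefied_12`, species with >= 10 loads only, NA
otherwise). The digits of this table were concatenated in the available
text extraction; they were de-concatenated using the per-species load
counts of the meta table as a cross-key, and the transcription reproduces
the published column means (6.9 / 13.6 plant species, 3.4 / 7.6 families)
and Mann–Whitney statistics (W = 211.5 and 151.5) exactly. The published
text quotes a standard error of 0.9 for observed plant species where the
table's average row prints 1.0; the value computed from this transcription
is 0.985.
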