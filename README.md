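# depredate

Quantifying marine-mammal depredation on demersal longline fisheries from
per-set observer records.

Toothed whales — above all orcas (*Orcinus orca*), and to a lesser degree
sperm whales and Antarctic fur seals — remove hooked fish from longlines
while the gear is hauled. In the Patagonian toothfish (*Dissostichus
eleginoides*) fishery around South Georgia this *depredation* cuts catch
rates on affected lines, biases stock assessment if untreated, and
concentrates in small, seasonal "hot spots". `depredate` is an R package for
analysts of fishery-observer data who want to measure where, when and how
much catch is lost, using only per-set observer records (date, position,
hooks, catch mass, and per-species mammal counts and feeding flags).

## What it computes

With CPUE the catch per unit effort (kg of toothfish per hook) and OPUE the
observations per unit effort (animals per longline set in a spatial box),
the package provides:

* **Screening and binning** — observer-coverage and year filters; a
  dual-resolution spatial frame of 0.5° × 1° boxes and 10 km squares grouped
  into five named areas (Shag Rocks, North West, North East, South West,
  South East).
* **Scenario-stratified catch rates** — mean CPUE under predicates over
  species presence/feeding (e.g. "orcas feeding, sperm whales absent"),
  with a within-(area, month) permutation test for the presence effect.
* **Per-cell depredation percentage** — for each 10 km cell-month,
  `100 · (CPUE_clean − CPUE_orca) / CPUE_clean` over orca-absent and
  orca-present strata, valid only when both strata have N > 3 sets.
* **Hot spots** — valid cells whose depredation percentage exceeds the
  monthly mean + 1 sample SD.
* **Nearest-unaffected matching** — per depredated line, the CPUE reduction
  against the spatio-temporally nearest orca-free line
  (cost = km + 25 km/day · days).
* **Track chaining** — same-day orca observations within 50 km of each other
  chained into potential vessel-following tracks; singletons discarded.
* **Energetics** — daily toothfish requirement (100 kg female / 124 kg male,
  184 kcal/100 g) and the fraction of it covered by observed per-orca take.
* **A synthetic fishery simulator** — observer-style records with known
  ground truth (true catch, multiplicative depredation `δ`, pod identity),
  emulating the winter season, region, hook counts, area-level catch rates
  and encounter frequencies of the South Georgia fishery, so every stage is
  testable end to end without confidential observer data.

## Worked example

Simulate a month of dense fishing with a fleet-trailing orca pod removing
40 % of the catch on depredated sets, then re-estimate that loss from the
records alone:

```r
library(depredate)

cfg <- simulation_preset("recovery", seed = 1, delta = 0.4)
sim <- simulate_season(cfg)          # 1,984 sets, ground truth attached
sets <- screen_sets(sim$sets)$sets   # observer-covered sets only

stats <- cell_depredation(sets, min_stratum_sets = 20)
mean(stats$pct_depredation[stats$valid])
#> [1] 39.7   (17 valid cells; the simulated loss was 40%)

detect_hotspots(stats)[, c("cell_i", "cell_j", "pct_depredation", "threshold")]
#> # A tibble: 3 × 4
#>   cell_i cell_j pct_depredation threshold
#> 1      4     14            49.5      46.7
#> 2      4     15            47.8      46.7
#> 3      5     15            55.8      46.7
```

The three hot spots are the cells where depredation exceeded the monthly
mean + 1 SD threshold (46.7 %). The presence effect is highly significant
under the stratified permutation null:

```r
presence_effect_test(bin_sets(sets, strict = FALSE), "orca", 999, seed = 1)
#> observed_diff = -0.0848 kg/hook, p = 0.001
```

and the same records chain into vessel-following tracks:

```r
obs <- sim$sets[sim$sets$orca_n > 0, c("set_id", "date", "lat", "lon", "haul_order")]
tracks <- build_daily_tracks(obs)    # 122 tracks, ~7 links each
```

On the energetics side, an observed take of 120 kg per orca per depredated
line covers a 50/50 female/male pod's daily requirement:

```r
coverage_fraction(120, frac_female = 0.5)
#> [1] 1.071
```

Published annual interaction tables can be summarised with the same
machinery: `add_summary_rows(published_annual_summary())` reproduces the
long-run means (orcas on 4.73 % of sets per year, sperm whales 25.48 %, fur
seals 8.91 %) and totals (1,688 orca-affected sets, 13,562 orcas) of the
1997–2012 South Georgia observer series.

The full chain (simulate → screen → bin → summarise → depredation → hot
spots → tracks → energetics) runs as one reproducible step with
`run_pipeline(config, out_dir)`, which writes every stage as CSV plus a
manifest of file checksums.

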