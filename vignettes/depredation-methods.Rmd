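---
title: "Methods: quantifying longline depredation by marine mammals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying longline depredation by marine mammals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depredate)
```

## The problem and the data model

Depredation is the removal of hooked fish from fishing gear by predators
during hauling. In the winter Patagonian toothfish fishery around South
Georgia the relevant predators are orcas, sperm whales and Antarctic fur
seals, and the unit of observation is the *longline set*: one deployment and
haul of a weighted line of hooks, recorded by a scientific observer as a
date, a position, a hook count, a toothfish mass, and per-species animal
counts with feeding flags. `depredate` takes a table of such per-set records
(one row per set, mammal observations flattened to `orca_n`/`orca_feeding`
and so on) and derives spatially and temporally resolved depredation
statistics from it.

Two normalised rates underlie everything:

* **CPUE** (catch per unit effort), kg of toothfish per hook,
  `catch_kg / hooks`, reported in figures as g/hook;
* **OPUE** (observations per unit effort), animals of a species per longline
  set within a spatial group, which corrects sighting counts for where and
  how often the fleet fishes. By default the numerator is animal counts (so
  OPUE matches "animals per set" ratios in annual interaction tables); an
  `events` option counts sets-with-observations instead.

### Screening

Standard data preparation drops sets without observer coverage and sets from
configured excluded years (default: 1996, the first, inconsistent observer
year of this fishery), and clears observations of species outside the three
focal ones. Sets with *no* mammals are always retained — they are the
comparison stratum, not noise. The screening report reconciles exactly:
input = retained + dropped, by category.

### One record = one set

Observer data sometimes aggregate 1–3 physical lines per "set". The package
treats one record as one set throughout; if line-level records are
available they can be passed directly, since nothing in the statistics
assumes a particular gear granularity beyond the hooks column.

## The spatial frame

Analyses run on a dual-resolution frame over the 34–45°W, 53–56°S region:

* **0.5° × 1° boxes** for seasonal abundance (OPUE) maps;
* **10 km squares** for catch-rate and depredation surfaces, built in a
  local equirectangular projection
  `x = (lon − lon₀)·111.320·cos(lat₀)`, `y = (lat − lat₀)·110.574` km about
  a configurable origin (default −54.5, −39.5). Over a 3° latitudinal span
  the scale distortion of this projection is below 2 %, negligible against
  the 10 km cell size; the projection is swappable if a study region ever
  warrants it.

All binning is floor-based on half-open `[low, high)` intervals with 0-based
indices, so edge points belong deterministically to the larger-index cell.
Great-circle distances are haversine on a 6371 km sphere (via `geosphere`);
geodesic (ellipsoidal) distances would change 50 km-scale values by far less
than the positional uncertainty of a hauling vessel.

The five named areas (Shag Rocks, North West, North East, South West, South
East) are conventionally shown on maps without published boundary
coordinates. The default scheme here is therefore an explicit, configurable
approximation of that layout: Shag Rocks west of −40°; the remainder split
at −54.4° latitude and −36.5° longitude. All area-stratified results are
relative to the configured scheme, which is serialised with every pipeline
run.

## Depredation statistics

**Scenario algebra.** A scenario constrains each focal species to one of
`ANY`, `PRESENT`, `ABSENT`, `FEEDING` (present and feeding) or
`NOT_FEEDING`; a set matches when all three predicates hold. The shipped
catalogue (`default_scenarios()`: the no-mammal baseline, all marginal
states, pairwise and triple presence) is a plain named list — analyses
routinely add combinations, and nothing depends on the catalogue's length.

**Per-cell depredation percentage.** For a 10 km cell-month with orca-absent
("clean") and orca-present strata,

\[ \mathrm{pct} = 100\,\frac{\overline{\mathrm{CPUE}}_{clean} -
\overline{\mathrm{CPUE}}_{orca}}{\overline{\mathrm{CPUE}}_{clean}} \]

computed on stratum means of per-set CPUE (matching "catch rates" usage; a
pooled-catch/pooled-hooks variant would weight big lines more and answer a
different question). A cell-month is *valid* only when both strata contain
more than 3 sets and the clean mean is positive; the threshold applies to
both strata deliberately — the percentage is a ratio of two noisy means, and
a deep orca stratum cannot rescue a two-set clean stratum. Invalid cells are
flagged, never silently dropped.

**Hot spots.** Within each month, valid cells whose percentage exceeds the
mean + 1 *sample* (n−1) standard deviation of valid-cell percentages. The
threshold is computed per month rather than pooled, because both the
fishery's footprint and the predators' distribution shift month to month; a
pooled threshold would mostly flag the high-CPUE-contrast months. The
output is invariant to cell order and to the presence of invalid cells.

**Nearest-unaffected matching.** A depredated line is compared with the
orca-free line minimising `haversine_km + w·|Δdays|`. The exchange rate `w`
(default 25 km/day) is a matching weight, not a biological speed: it sets
how many kilometres of separation one is willing to trade for a day of
separation when choosing a counterfactual line. Ties break by set id for
determinism, and a zero-CPUE match flags the reduction as undefined.

**Presence permutation test.** In place of model-based inference, the
package tests a species' effect on CPUE by permuting the presence flag
within (area, month) strata, holding spatial and seasonal catch-rate
structure fixed. The statistic is the difference of stratum-pooled means;
the two-sided p-value carries the add-one correction. Strata with a single
presence class are uninformative and dropped with a warning. This is a
design-based complement to — not a re-implementation of — mixed-model
analyses of such data.

**Annual summary.** Per year and species: sets with observations, total
animals, percent of sets observing, and animals per set, plus a column-mean
`average` row and a column-sum `total` row (counts only). Report rounding is
2 decimals, half-up — `round_half_up()` — because that is how such tables
are conventionally printed; base R's round-half-to-even would differ on
exact halves.

**Intensity–interaction correlation.** Across 10 km cells in a month, the
Pearson correlation (with `cor.test`) between lines per cell and orcas per
line per cell. Absence of correlation argues against hauling sound being
the primary draw of orcas into an area.

## The energetics budget

The daily toothfish requirement is parameterised at 100 kg (female) and
124 kg (male) per orca per day with 184 kcal/100 g raw toothfish.
`coverage_fraction(take, frac_female)` divides an observed per-orca daily
take by the sex-weighted requirement; it is linear in the take and
decreasing in the male share. The population-level question — what fraction
of a resident population's needs depredation could cover — depends on the
(unpublished) population size and total loss, so the package exposes the
calculation with those as inputs rather than asserting any particular band.

## The synthetic fishery

The simulator exists so that every stage can be exercised against known
ground truth. Per day, each of `n_vessels` (default 12, the order of the
real fleet's seasonal cruise count) hauls `sets_per_vessel_day` sets near
its position; vessels random-walk (step 15 km/day) and relocate to a fresh
ground with probability 0.4/day, biased toward areas with higher baseline
catch rates — a fleet practising move-on avoidance mixes quickly. Defaults
emulate the study fishery: season 16 April–14 September; hooks lognormal
with median 7,000 clamped to [1,000, 36,000]; area baselines 233–300 g/hook;
multiplicative lognormal CPUE noise (σ = 0.5, mean-one) with a 2 %
zero-catch probability; 87 % observer coverage.

Pods move along seasonal waypoint paths (parameterised as fractions 0–1 of
the season, so the same drift works for any configured season) with a
bounded daily displacement, or optionally trail the fleet. Default pods
reproduce the qualitative seasonal pattern: orcas (four pods of 8–10) on
the north coast in May/June drifting to Shag Rocks by August; sperm whales
(eight pods of 2–3); fur seals (six pods of 8–10) north early and
south-west late. Pod sizes mirror typical group sizes at lines.

**Encounters.** A pod within its species' `encounter_radius_km` of a
hauling set may visit it; whether it does is an independent Bernoulli draw
with propensity `p_interact`. The radius is held at a same-day interaction
range (150 km — pod positions are group-day centroids and lines are hauled
over many hours), and the propensity is the tuning knob: the realised
encounter rate is close to linear in it, whereas using a tight hard radius
as the knob couples the rate to the particular pod–fleet geometry of a seed
and makes it unstable between runs. `calibrate_to_encounter_rates()`
bisects the propensity (log scale, averaging a few pilot replicates) until
simulated rates match targets — by default the long-run South Georgia
rates: orcas on 4.7 % of observed sets, sperm whales 25 %, fur seals 8.9 %.
Rates remain monotone in radius, propensity and pod count.

**Depredation.** On orca encounter, feeding is certain by default
(`p_feed_given_encounter = 1`): depredated catch rates are lower whether or
not feeding is *observed*, so observation noise belongs on the flag, which
is set with probability `p_observe_feeding = 0.9`. The recorded catch is
exactly `true × (1 − δ)` on fed sets (`δ` = `depredation_multiplier`), and
the ground-truth log (true catch, δ applied, pod identity) joins losslessly
by set id — conservation is exact by construction, and tested.

**What the simulator does not emulate.** Real per-set catch distributions
are unknown (the observer data are confidential); lognormal-with-zeros is
an assumption, not an estimate. There is no krill or oceanographic forcing,
no vessel economics, no gear-type differences beyond hook counts, no
individual (photo-ID) structure within pods, and encounter geometry is
deliberately smoothed for cross-seed stability. Passing recovery tests on
synthetic data therefore demonstrates that the *estimators* are correct
under the stated generative assumptions — not that those assumptions hold
in any real fishery.

One consequence of the smoothed encounter geometry: observation positions
smear toward the fleet, so the monthly OPUE-weighted centroid of simulated
orca observations tracks the configured waypoint path on seasonal average
(mean monthly error under 50 km, with the May→August westward drift clearly
recovered) rather than pinning each individual month to the path.

## Numerical and testing choices

* All randomness flows from one seed through R's generator; simulations,
  permutation tests and the pipeline are exactly reproducible, and the
  pipeline manifest records file checksums to prove it.
* Degenerate inputs are contracts, not crashes: zero candidate matches,
  sub-minimum strata, < 2 valid cells, zero-variance correlations and
  unreachable calibration targets all return flagged results or structured
  warnings.
* Test problem sizes are chosen for depth per second: the chaining oracle
  runs 1,000 random days of ≤ 12 observations against an independent
  brute-force scan; partition checks scan the region at 0.05°; the
  depredation-recovery design uses ~2,000 sets in a ~55 × 65 km patch so
  each 10 km cell accumulates ≥ 20 sets per stratum (at that depth the
  recovered percentage sits within a few points of 100·δ); calibration
  pilots use ~5,000 sets. The whole suite runs in well under a minute.

## Known limitations

* The five-area boundaries are an approximation; results stratified by area
  are only comparable across studies using the same scheme.
* The depredation percentage is a ratio of stratum means; at the minimum
  stratum depth (4) it is noisy, and cells near the threshold flip validity
  between months. Hot-spot membership inherits that noise.
* The permutation test conditions on (area, month) strata; finer
  confounding (vessel skill, within-month trends) is not controlled.
* Track chaining is a feasibility argument — same group, reachable
  distances — not an identification of individuals.
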