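# elevdiv

Elevational gradients of taxonomic and phylogenetic plant diversity, as a
tested, tidyverse-style R pipeline.

Mountain floras are usually documented by heterogeneous occurrence records
(herbarium specimens, survey plots, literature) that carry an elevation for
each observation. `elevdiv` turns such records into the standard
elevational-gradient analysis used in community ecology and
community phylogenetics:

* **Cleaning** — synonym resolution against a local table, removal of
  records without elevation, collapse of exact duplicates (same accepted
  name, mountain, elevation rounded to 1 m), optional out-of-span filtering,
  with an exact accounting report.
* **Belts** — each mountain's span is partitioned into 100-m elevational
  belts (half-open `[lo, lo+100)`, summit belt closed), and a belt × taxon
  presence/absence matrix is built under either a record-based or a
  range-through occupancy rule.
* **Alpha diversity** — per belt: species richness *SR*; Faith's
  phylogenetic diversity `PD(S) = Σ branch lengths of the (root-anchored)
  subtree spanning S`; phylogenetic endemism
  `PE(belt) = Σ_b L_b / r_b` over branches *b* touching the belt, where
  `r_b` is the number of belts occupied by the branch's descendants
  (Rosauer-style range weighting). Summed over belts, PE returns PD of the
  whole flora exactly.
* **Beta diversity** — for adjacent belts, Jaccard similarity
  `β_j = c / (a + b + c)` (a, b = species unique to each belt, c = shared)
  and Cody turnover `β_c = (|A| + |B| − 2c) / 2`; literal variants of both
  formulas are selectable for comparison.
* **Phylogenetic structure** — mean pairwise patristic distance (MPD) and
  the net relatedness index
  `NRI = −(MPD_obs − mean MPD_null) / sd MPD_null` under a randomization
  null (default: 1000 communities drawn uniformly from the mountain's
  species pool; a tip-label-shuffling scheme is also available). NRI > 0
  means phylogenetic clustering, NRI < 0 overdispersion.
* **Trends** — quasi-Poisson GLMs (log link, deviance pseudo-R²) for
  richness ~ belt area, Gaussian fits for NRI ~ elevation and
  NRI ~ richness, Pearson correlation of native vs non-native belt
  richness, and cross-mountain determinants of the richness-peak elevation
  (relative elevation, longitude, temperature, precipitation).
* **Synthetic data** — a generator for Yule phylogenies, per-species
  elevational ranges under five scenarios (neutral, habitat filtering at
  the base or summit, mid-slope hump, base-anchored monotonic decrease),
  occurrence records with realistic cleaning hazards, belt-area profiles
  and coupled non-native subsets, so every stage is testable offline.

## Worked example

A small synthetic mountain (20 species, 0–800 m, hump-shaped richness)
ships as plain-text files under `inst/extdata/` (all `synthetic_*`):

```r
library(elevdiv)
ext <- function(f) system.file("extdata", f, package = "elevdiv")

cfg <- run_config(
  "synthetic_toy",
  occurrences = ext("synthetic_occurrences.csv"),
  tree        = ext("synthetic_tree.nwk"),
  areas       = ext("synthetic_belt_areas.csv"),
  aliens      = ext("synthetic_alien_list.txt"),
  min_elev = 0, max_elev = 800,
  occupancy_mode = "record", n_reps = 999, seed = 42)
res <- run_mountain(cfg)

res$cleaning_report
#> Occurrence cleaning report
#>   records in:           192
#>   no elevation removed: 4
#>   duplicates collapsed: 20
#>   records out:          168

res$profile
#> # A tibble: 8 x 9
#>   mountain_id    belt    lo    hi midpoint    sr    pd    pe area_km2
#> 1 synthetic_toy     1     0   100       50     1  2.50 0.367     13.8
#> 2 synthetic_toy     2   100   200      150     5  7.93 1.30      56.8
#> 3 synthetic_toy     3   200   300      250     8  8.93 1.52     169.
#> 4 synthetic_toy     4   300   400      350    13 13.9  3.05     263.
#> 5 synthetic_toy     5   400   500      450    12 12.6  3.04     260.
#> 6 synthetic_toy     6   500   600      550    12 16.2  4.02     167.
#> 7 synthetic_toy     7   600   700      650     9 13.3  3.14      58.3
#> 8 synthetic_toy     8   700   800      750     4  7.01 1.15      12.7

res$peak_m
#> [1] 350
```

Richness, PD and PE all peak mid-slope (belt 300–400 m, midpoint 350 m),
tracking the hump in belt area. The trend table confirms the area effect
and finds no significant NRI gradient on this small flora:

```r
res$trends
#> # A tibble: 3 x 9
#>   response predictor family        slope pseudo_r2 pearson_r2 p_value     n extra
#> 1 sr       area_km2  quasipoisson 0.00459    0.635      0.710  0.0161     8 NA
#> 2 nri      midpoint  gaussian    -0.00155    0.173      0.173  0.354      7 flat
#> 3 nri      sr        gaussian    -0.0956     0.179      0.179  0.345      7 NA
```

The quasi-Poisson slope of richness on belt area is positive
(p = 0.016, pseudo-R² = 0.64): belts with more area hold more species.
Per-belt NRI (`res$nri`) is computed against 999 pool-draw null
communities; belt 1 holds a single species and is reported as not
evaluable rather than silently dropped.

`plot_diversity_profile(res$profile)`, `plot_beta_profile(res$beta,
res$matrix)` and `plot_nri_profile(res$nri)` draw the three standard
panels; `autoplot()` works on any fit returned by the trend functions, and
`tidy()`/`glance()` give broom-style summaries.

For multi-mountain syntheses, `run_cross_mountain()` combines at least
four completed runs into the species/genus/family summary table
(min/max/half-up-rounded mean via `cross_mountain_stats()`), the
richness-peak table, and single-predictor determinant fits of peak
elevation on mountain attributes.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end analysis from scratch: it simulates
eight synthetic mountains with the spans of a typical subtropical transect
(1474–3106 m) across the generator's scenarios, runs the full
single-mountain pipeline on each (cleaning through NRI and trend fits,
199 null replicates), synthesizes them with `run_cross_mountain()`, and
writes the report JSON to `--out`. All randomness derives from `--seed`.

## Vignette

`vignettes/elevational-diversity.Rmd` documents the model and conventions
in detail: occupancy rules, the β-diversity formula variants, the NRI null
schemes and their equivalence, pseudo-R² choices, what the synthetic
generator does and does not emulate, and known limitations.
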