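---
title: "Elevational diversity gradients: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elevational diversity gradients: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`elevdiv` implements the standard analysis of plant diversity along
mountain elevational gradients: occurrence-record cleaning, 100-m belt
binning, taxonomic and phylogenetic alpha-diversity, adjacent-belt
beta-diversity, null-model phylogenetic structure, and the regression
models that relate these profiles to belt area, elevation, and mountain
attributes. This vignette records the model choices, the parameters that
matter, and exactly what the synthetic-data generator does and does not
establish.

## The data model

An occurrence record is one observation of a taxon on a mountain at an
elevation in metres. After cleaning, records are binned into elevational
belts of width 100 m (configurable). Belts are half-open intervals
`[lo, lo + w)` anchored at the mountain's declared minimum elevation, with
the summit belt closed and truncated at the maximum, so a record at an
exact multiple of the belt width belongs to one belt only and the summit
itself is never lost. The belt grid is *not* anchored at sea level unless
the declared minimum is 0; whether published studies anchor at the base or
at sea level is usually unstated, so the anchor is explicit here.

Two occupancy rules build the belt-by-taxon presence/absence matrix:

* `record` (default): a species occupies exactly the belts containing at
  least one of its records. This is faithful to specimen evidence and is
  the default because interpolation is an assumption, not data.
* `range_through`: a species occupies every belt between its lowest and
  highest record. This is the common convention in elevational-gradient
  studies and is what the synthetic generator's truth record uses.

Range-through occupancy is always a superset of record occupancy; every
output records which rule produced it.

## Cleaning

Cleaning applies, in order: synonym mapping through a local two-column
table (no network services; the mapping never touches a record's mountain
or elevation), removal of records lacking an elevation, removal of records
outside the declared span (unless `keep_out_of_span`), and collapse of
exact duplicates, defined as identical accepted name, mountain, and
elevation rounded to 1 m. Published cleaning protocols say only "duplicate
records"; 1-m rounding is this package's operational definition and is
echoed in every run manifest. Names absent from the taxonomy backbone are
kept verbatim by default and only dropped on request, so synthetic data
needs no backbone. The cleaning report satisfies
`n_in − (no_elevation + out_of_span + duplicates + unresolved_dropped) =
n_out` exactly, and cleaning is idempotent.

## Alpha diversity

*Species richness* is the count of distinct accepted names per belt.

*Faith's PD* is the sum of branch lengths of the minimal subtree spanning
the belt's taxa. By default the subtree is anchored at the root — the
convention of the community-phylogenetics toolchain most gradient studies
use — so a single-species belt has PD equal to that species' root-to-tip
path. `include_root = FALSE` restricts to branches below the set's MRCA.
Zero-length branches are permitted and contribute 0.

*Phylogenetic endemism* divides each branch length by its range size
before summing. Because the analysis is one mountain's gradient, range
size is measured in belts: `r(b)` is the number of belts in which at least
one descendant tip of branch *b* occurs, and
`PE(belt) = Σ_{b touching belt} L_b / r(b)`. The `1/r(b)` weights are an
exact partition of each branch's length across the belts that hold it, so
`Σ_belts PE = PD(whole flora)` to numerical precision — this identity is
asserted in the tests at 1e-9 relative tolerance and is the package's main
internal check on the branch-range bookkeeping.

## Beta diversity

The printed formulas for the two indices in the gradient literature are
often ambiguous: defining `a` and `b` as the *total* richness of the two
communities makes Jaccard similarity of identical communities less than 1.
The package therefore defaults to the internally consistent reading —
`a`, `b` are the species *unique* to each belt, `c` the shared count —
giving the standard Jaccard `c/(a+b+c)` and Cody `(|A|+|B|−2c)/2`, and
offers the literal variants (`literal_totals`, `over_c`) for comparison
without asserting either as any author's intent. Empty belts are skipped
with a warning, not treated as zero-similarity communities.

## Phylogenetic structure

MPD is the mean patristic distance over all unordered pairs in a belt.
The net relatedness index standardizes it against `n_reps` (default 1000)
randomized communities of the same size:

`NRI = −(MPD_obs − mean(MPD_null)) / sd(MPD_null)`

Positive NRI means co-occurring species are more closely related than
chance (clustering, the habitat-filtering signature); negative means
overdispersion. Choices worth recording:

* **Null scheme.** The default draws communities uniformly without
  replacement from the mountain's species pool (`pool_draw`, the literal
  reading of "randomly generated communities from a given species pool").
  A tip-label-shuffling scheme is also provided because the standard
  software default shuffles labels. For MPD the two induce the same null
  distribution — both reduce to a uniform k-subset of the pool — and the
  tests verify both against exact enumeration.
* **Pool.** All species recorded on that mountain, not a multi-mountain
  union; each mountain gets its own pruned tree.
* **Null sd.** The sample (n−1) standard deviation of the replicate MPDs.
* **Degenerate nulls** (zero sd: star trees, or community = pool under
  label shuffling) yield `NRI = NA` with an explicit flag, never a silent
  zero.
* **rank_p** is the left-tail rank probability
  `(1 + #{null ≤ obs}) / (n_reps + 1)`: small values indicate clustering.
* **Reproducibility.** Per-belt seeds are derived deterministically from
  the run seed, so profiles are bit-identical across runs and independent
  of belt evaluation order. Library calls without a seed draw one and
  report it.

NRI is invariant to uniform branch-length rescaling, and on pools of ≤ 8
tips the Monte-Carlo estimate is tested against brute-force enumeration of
all possible communities, with a delta-method Monte-Carlo standard error
that uses the exact null's skewness and kurtosis (the null MPD
distribution is discrete and skewed, so a normal-theory error bar is too
narrow).

## Trend models

Count responses (richness on belt area, peak elevation on mountain
attributes) use quasi-Poisson GLMs with log link, dispersion from the
Pearson statistic, and a t-test on the slope. Published gradient analyses
report an "R²" from these GLMs without defining it; the package reports
the deviance pseudo-R² `1 − D_resid/D_null`, and carries the squared
Pearson correlation of fitted vs observed alongside for comparison.

NRI is real-valued, so NRI ~ elevation and NRI ~ richness use ordinary
least squares even though the source analyses name GLMs; the family is
recorded in every fit row. The elevation trend classifies each mountain at
α = 0.05 as clustering-increasing, clustering-decreasing, or flat.

The richness peak is the midpoint of the belt with maximal richness, ties
resolving to the lowest belt (peaks are conventionally reported as 100-m
ranges, consistent with a midpoint). Peak determinants are four
single-predictor fits (relative elevation, longitude, annual mean
temperature, annual precipitation); no multiple-testing correction is
applied across them — none is applied in the analyses this mirrors — and
the output says so. The determinant family defaults to quasi-Poisson to
match the source convention; a Gaussian option exists because peak
elevations are not counts, and the exact-recovery tests use it.

Cross-mountain summary means are rounded half-up to integers: this is the
rounding that reproduces typical printed flora tables exactly (e.g.
1977.5 → 1978), where IEEE round-half-even would not.

## The synthetic generator

The generator exists so that every stage is testable without herbarium
downloads. Defaults describe a plausible subtropical mountain flora:
200 species on a 0–2000 m span; ~10 records per species (regional
herbarium datasets run roughly 5–17 records per species); 20 m elevation
noise (altimeter/plot-interval error); 10% duplicate rows and 5% missing
elevations (the two dominant cleaning hazards); 5% non-native species
(regional alien floras are 2–6%) with strong belt-level coupling to native
richness, the empirically observed pattern.

Scenarios shape expected richness: `neutral` places range midpoints
uniformly with lognormal widths clipped to the span (mid-domain constraint
only); `mid_peak` concentrates midpoints mid-slope; `filter_low` /
`filter_high` confine one randomly chosen clade (≥ 20% of tips) to the
bottom/top third of the span, so those belts receive closely related
species and their expected NRI rises — the tests confirm the top-belt NRI
separation from neutral across 100 replicates. `monotonic_decrease` is
generated as base-anchored nested attrition: every range starts at the
mountain base with a lognormal width. This makes expected belt richness
non-increasing *by construction* (each higher belt's flora is a subset of
the one below in expectation), which is the classic mechanism behind
monotonically declining mountain floras and guarantees the richness peak
sits in the lowest belt without any tuning.

Hazard injection has two deliberate asymmetries:

* Each species always receives records at its two range endpoints, and
  elevation blanking applies only to non-endpoint records (unless the rate
  is exactly 1, which blanks everything and makes the cleaner refuse the
  file). This guarantees that at zero elevation noise the range-through
  belt occupancy is recovered *exactly* after cleaning, for any duplicate
  or missing rate below 1 — the end-to-end recovery test — while a
  rate of 1 still exercises the "no usable records" failure path.
* Duplicates are appended as `Binom(n, r/(1−r))` extra copies of existing
  rows, so the duplicate fraction of the *emitted file* is approximately
  the configured rate and the cleaner's duplicate count admits a binomial
  check against it.

Non-native assignment labels a uniform fraction of species and redraws
their (narrower) ranges: with probability equal to `nonnative_coupling`
the new midpoint is sampled from the native richness density (a uniform
point inside a uniformly chosen native range), otherwise uniformly on the
span. At coupling 1 this makes belt-level non-native richness track native
richness strongly; at coupling 0 the two profiles are generated
independently. A caveat the tests make visible: even at coupling 0 a small
positive correlation remains, because any interval placed in a bounded
domain has depressed expected coverage near the boundaries (the mid-domain
effect), and both groups share those boundaries. The replicate-mean
correlation stays within its Monte-Carlo error of zero, but it is a
geometric residual, not exactly zero.

What the generator does **not** emulate: spatial (latitude/longitude)
structure, climate fields, collection-effort gradients along elevation,
taxonomic error beyond the synonym table, speciation-gradient or
birth–death extinction dynamics (pure-birth trees suffice because every
statistic consumes only tree shape and branch lengths), and
abundance — all matrices are presence/absence. A green test on synthetic
data therefore establishes the *statistical machinery*, not the ecology of
any real mountain.

## Numerical and degenerate-input choices

* Belt index of an elevation `e` is `floor((e − anchor)/w) + 1`, with the
  summit mapped into the top belt; out-of-span records error unless
  explicitly kept.
* PE of an empty belt is 0 with a warning; NRI of a belt with < 2 taxa is
  reported as not evaluable rather than dropped, so profiles keep one row
  per belt.
* Quasi-Poisson fits refuse all-zero responses and non-convergence after
  100 IRLS iterations; non-integer responses fit with a warning.
* All seeds are 32-bit integers; derived child seeds use a fixed linear
  map modulo 2³¹ − 1 so multi-stage runs stay reproducible and
  order-independent.
* The acceptance-style scenario-separation check runs at the generator's
  stated world (100 replicates, 200 species, 0–2000 m) but with 199 null
  replicates per belt rather than 1000: the criterion constrains replicate
  count and world size, not null depth, and 199 keeps the suite inside a
  desktop time budget.

## Known limitations

* Single-predictor models only; no model selection, multi-predictor fits,
  or spatial autocorrelation corrections.
* No abundance weighting (MPD/PD are presence-based), no NTI/MNTD, and no
  occupancy-constrained (independent-swap) null models.
* Synonym resolution is exact-match against the supplied table; no fuzzy
  matching.
* Belt areas and mountain attributes are inputs; the package does no GIS.
* With eight or fewer mountains the determinant fits have very low power;
  their p-values should be read accordingly.
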